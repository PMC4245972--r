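# Idealized ribonucleotide heavy-atom templates (strand I) in the
# standard Watson-Crick base-pair reference frame: origin on the
# pseudo-dyad, x toward the major groove, y toward the strand-I C1',
# base plane z = 0. The strand-II partner of base b is the (x,-y,-z)
# flip of the template of the complementary base.
# Monomer geometry: Chemical Component Dictionary idealized
# coordinates, glycosidic torsion chi set to -160 deg (anti, A-form),
# rigidly superposed on the standard base frame by base heavy atoms.
# Columns: base, atom name, x, y, z in Angstrom.
base,atom,x,y,z
A,C1',-2.4255,5.4298,-0.0014
A,C2,-1.9349,0.9684,-0.0001
A,C2',-2.9386,5.6460,1.4394
A,C3',-3.3821,7.1262,1.4602
A,C4,-1.2831,3.1714,-0.0001
A,C4',-3.0875,7.6267,0.0294
A,C5,0.0611,2.7616,0.0056
A,C5',-2.5859,9.0713,0.0591
A,C6,0.3338,1.3831,-0.0009
A,C8,0.0467,4.9296,-0.0010
A,N1,-0.6882,0.5347,-0.0003
A,N3,-2.2388,2.2488,-0.0003
A,N6,1.6380,0.9201,-0.0013
A,N7,0.8197,3.8830,-0.0005
A,N9,-1.2602,4.5433,-0.0011
A,O2',-4.0457,4.7866,1.7180
A,O3',-4.6725,7.5634,1.8894
A,O4',-2.0561,6.7457,-0.4653
A,O5',-1.4690,9.1709,0.9423
A,OP1,-2.0543,11.5964,1.3158
A,OP2,-0.5306,11.0620,-0.6230
A,P,-0.9620,10.6978,0.8841
C,C1',-2.4745,5.3987,0.0005
C,C2,-1.4575,3.1905,0.0000
C,C2',-2.9877,5.6071,1.4421
C,C3',-3.4488,7.0832,1.4650
C,C4,0.8284,2.8570,-0.0008
C,C4',-3.1617,7.5887,0.0341
C,C5,1.0289,4.2526,0.0038
C,C5',-2.6757,9.0383,0.0644
C,C6,-0.0499,5.0703,-0.0024
C,N1,-1.2985,4.5251,-0.0004
C,N3,-0.4061,2.3721,-0.0004
C,N4,1.9068,2.0036,-0.0008
C,O2,-2.5830,2.7196,0.0010
C,O2',-4.0852,4.7361,1.7219
C,O3',-4.7441,7.5071,1.8952
C,O4',-2.1203,6.7197,-0.4630
C,O5',-1.5584,9.1489,0.9460
C,OP1,-2.1703,11.5680,1.3215
C,OP2,-0.6431,11.0510,-0.6205
C,P,-1.0688,10.6815,0.8876
G,C1',-2.4181,5.4883,0.0006
G,C2,-1.9653,1.0327,-0.0009
G,C2',-2.9311,5.7013,1.4412
G,C3',-3.3779,7.1816,1.4624
G,C4,-1.2709,3.2350,0.0002
G,C4',-3.0846,7.6839,0.0330
G,C5,0.0668,2.8265,-0.0002
G,C5',-2.5852,9.1287,0.0635
G,C6,0.3521,1.4412,-0.0010
G,C8,0.0563,4.9938,0.0002
G,N1,-0.6829,0.5734,0.0052
G,N2,-2.9969,0.1274,-0.0016
G,N3,-2.2438,2.3166,-0.0002
G,N7,0.8297,3.9473,0.0000
G,N9,-1.2511,4.6031,0.0001
G,O2',-4.0372,4.8404,1.7185
G,O3',-4.6696,7.6169,1.8923
G,O4',-2.0511,6.8052,-0.4624
G,O5',-1.4677,9.2300,0.9464
G,O6,1.5039,1.0410,-0.0017
G,OP1,-2.0571,11.6544,1.3204
G,OP2,-0.5342,11.1239,-0.6192
G,P,-0.9639,10.7574,0.8883
U,C1',-2.4671,5.3256,-0.0019
U,C2,-1.3984,3.1435,0.0022
U,C2',-2.9819,5.5283,1.4399
U,C3',-3.4819,6.9890,1.4581
U,C4,0.9236,2.8786,-0.0003
U,C4',-3.2086,7.5009,0.0269
U,C5,1.0721,4.2854,0.0009
U,C5',-2.7566,8.9616,0.0523
U,C6,-0.0316,5.0634,0.0000
U,N1,-1.2696,4.4808,-0.0015
U,N3,-0.3144,2.3443,-0.0026
U,O2,-2.5077,2.6479,0.0006
U,O2',-4.0555,4.6280,1.7229
U,O3',-4.7860,7.3820,1.8903
U,O4,1.9041,2.1560,0.0006
U,O4',-2.1463,6.6542,-0.4689
U,O5',-1.6406,9.0997,0.9315
U,OP1,-2.3070,11.5050,1.3039
U,OP2,-0.7727,11.0201,-0.6404
U,P,-1.1860,10.6428,0.8692
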
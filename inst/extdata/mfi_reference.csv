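sample_id,donor_id,bead_id,mfi,role
S2,G1,GPIa/IIa,83.59,test
S2,G1,GPIba/IX,414.37,test
S2,G1,HLA,1399,test
S2,G1,GPIIb/IIIa,72.18,test
S2,G2,GPIa/IIa,89.70,test
S2,G2,GPIba/IX,468.21,test
S2,G2,HLA,438.5,test
S2,G2,GPIIb/IIIa,108.04,test
S2,G3,GPIa/IIa,52.42,test
S2,G3,GPIba/IX,71.95,test
S2,G3,HLA,334,test
S2,G3,GPIIb/IIIa,186.68,test
S2,G4,GPIa/IIa,46.49,test
S2,G4,GPIba/IX,69.51,test
S2,G4,HLA,1442,test
S2,G4,GPIIb/IIIa,58.83,test
S3,G1,GPIa/IIa,71.05,test
S3,G1,GPIba/IX,36.19,test
S3,G1,HLA,1390,test
S3,G1,GPIIb/IIIa,70.60,test
S3,G2,GPIa/IIa,57.32,test
S3,G2,GPIba/IX,68.15,test
S3,G2,HLA,2469,test
S3,G2,GPIIb/IIIa,74.08,test
S3,G3,GPIa/IIa,83.57,test
S3,G3,GPIba/IX,43.42,test
S3,G3,HLA,2776.5,test
S3,G3,GPIIb/IIIa,111.12,test
S3,G4,GPIa/IIa,941.90,test
S3,G4,GPIba/IX,71.25,test
S3,G4,HLA,1395,test
S3,G4,GPIIb/IIIa,71.52,test
T5,G1,GPIa/IIa,56.06,test
T5,G1,GPIba/IX,21.63,test
T5,G1,HLA,45.19,test
T5,G1,GPIIb/IIIa,3430.30,test
T5,G2,GPIa/IIa,59.48,test
T5,G2,GPIba/IX,43.65,test
T5,G2,HLA,116.05,test
T5,G2,GPIIb/IIIa,1053.89,test
T5,G3,GPIa/IIa,69.32,test
T5,G3,GPIba/IX,53.31,test
T5,G3,HLA,71.13,test
T5,G3,GPIIb/IIIa,1318.20,test
T5,G4,GPIa/IIa,33.28,test
T5,G4,GPIba/IX,36.64,test
T5,G4,HLA,45.39,test
T5,G4,GPIIb/IIIa,3997.51,test
S7,G1,GPIa/IIa,1402.07,test
S7,G1,GPIba/IX,39.17,test
S7,G1,HLA,109.89,test
S7,G1,GPIIb/IIIa,1355.66,test
S7,G2,GPIa/IIa,1410.06,test
S7,G2,GPIba/IX,34.86,test
S7,G2,HLA,111.47,test
S7,G2,GPIIb/IIIa,1406.88,test
S7,G3,GPIa/IIa,1114.12,test
S7,G3,GPIba/IX,40.45,test
S7,G3,HLA,33.44,test
S7,G3,GPIIb/IIIa,1297.48,test
S7,G4,GPIa/IIa,1498.50,test
S7,G4,GPIba/IX,79.59,test
S7,G4,HLA,106.75,test
S7,G4,GPIIb/IIIa,1810.53,test
T8,G1,GPIa/IIa,33.77,test
T8,G1,GPIba/IX,41.91,test
T8,G1,HLA,103.64,test
T8,G1,GPIIb/IIIa,1347.68,test
T8,G2,GPIa/IIa,52.63,test
T8,G2,GPIba/IX,90.44,test
T8,G2,HLA,3675.49,test
T8,G2,GPIIb/IIIa,1764.84,test
T8,G3,GPIa/IIa,52.21,test
T8,G3,GPIba/IX,47.67,test
T8,G3,HLA,2065.35,test
T8,G3,GPIIb/IIIa,92.82,test
T8,G4,GPIa/IIa,51.73,test
T8,G4,GPIba/IX,37.52,test
T8,G4,HLA,1078.52,test
T8,G4,GPIIb/IIIa,1153.10,test
S9,G1,GPIa/IIa,76.06,test
S9,G1,GPIba/IX,79.44,test
S9,G1,HLA,559.08,test
S9,G1,GPIIb/IIIa,876.67,test
S9,G2,GPIa/IIa,76.41,test
S9,G2,GPIba/IX,69.50,test
S9,G2,HLA,5511.44,test
S9,G2,GPIIb/IIIa,107.48,test
S9,G3,GPIa/IIa,61.12,test
S9,G3,GPIba/IX,79.00,test
S9,G3,HLA,1961.17,test
S9,G3,GPIIb/IIIa,785.68,test
S9,G4,GPIa/IIa,69.75,test
S9,G4,GPIba/IX,83.96,test
S9,G4,HLA,3080.16,test
S9,G4,GPIIb/IIIa,976.73,test
T10,G1,GPIa/IIa,69.80,test
T10,G1,GPIba/IX,23.18,test
T10,G1,HLA,71.49,test
T10,G1,GPIIb/IIIa,77.42,test
T10,G2,GPIa/IIa,74.64,test
T10,G2,GPIba/IX,38.32,test
T10,G2,HLA,69.92,test
T10,G2,GPIIb/IIIa,44.98,test
T10,G3,GPIa/IIa,70.63,test
T10,G3,GPIba/IX,31.47,test
T10,G3,HLA,69.48,test
T10,G3,GPIIb/IIIa,97.10,test
T10,G4,GPIa/IIa,1979.27,test
T10,G4,GPIba/IX,80.06,test
T10,G4,HLA,78.05,test
T10,G4,GPIIb/IIIa,54.36,test
S11,G1,GPIa/IIa,50.80,test
S11,G1,GPIba/IX,47.89,test
S11,G1,HLA,28.64,test
S11,G1,GPIIb/IIIa,423.74,test
S11,G2,GPIa/IIa,56.66,test
S11,G2,GPIba/IX,71.67,test
S11,G2,HLA,37.95,test
S11,G2,GPIIb/IIIa,1022.23,test
S11,G3,GPIa/IIa,93.93,test
S11,G3,GPIba/IX,80.44,test
S11,G3,HLA,64.35,test
S11,G3,GPIIb/IIIa,1248.52,test
S11,G4,GPIa/IIa,43.16,test
S11,G4,GPIba/IX,35.45,test
S11,G4,HLA,72.41,test
S11,G4,GPIIb/IIIa,1203.06,test
S12,G1,GPIa/IIa,35.40,test
S12,G1,GPIba/IX,22.88,test
S12,G1,HLA,3135.34,test
S12,G1,GPIIb/IIIa,91.55,test
S12,G2,GPIa/IIa,41.92,test
S12,G2,GPIba/IX,74.05,test
S12,G2,HLA,14619.87,test
S12,G2,GPIIb/IIIa,130.06,test
S12,G3,GPIa/IIa,31.82,test
S12,G3,GPIba/IX,68.35,test
S12,G3,HLA,11924.19,test
S12,G3,GPIIb/IIIa,85.82,test
S12,G4,GPIa/IIa,54.81,test
S12,G4,GPIba/IX,29.88,test
S12,G4,HLA,9249.19,test
S12,G4,GPIIb/IIIa,83.82,test
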
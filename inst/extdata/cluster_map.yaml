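# Editable channel -> cluster assignment for topographic aggregation.
# Nine clusters: AF F FC C CP P PO T and the sagittal midline S.
# Reconstructed from electrode-name prefixes (see cluster_for_channels());
# review before use on real recordings.
Fp1: AF
Fp2: AF
AF7: AF
AF3: AF
AF4: AF
AF8: AF
F7: F
F5: F
F3: F
F1: F
F2: F
F4: F
F6: F
F8: F
FC5: FC
FC3: FC
FC1: FC
FC2: FC
FC4: FC
FC6: FC
C5: C
C3: C
C1: C
C2: C
C4: C
C6: C
CP5: CP
CP3: CP
CP1: CP
CP2: CP
CP4: CP
CP6: CP
P7: P
P5: P
P3: P
P1: P
P2: P
P4: P
P6: P
P8: P
PO7: PO
PO3: PO
PO4: PO
PO8: PO
PO9: PO
PO10: PO
O1: PO
O2: PO
FT9: T
FT7: T
T7: T
TP7: T
FT10: T
FT8: T
T8: T
TP8: T
AFz: S
Fz: S
FCz: S
Cz: S
CPz: S
Pz: S
POz: S
Oz: S
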
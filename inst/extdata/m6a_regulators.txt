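# RNA m6A regulator gene set: writers, erasers, readers and associated
# initiation/binding factors commonly screened in islet transcriptome studies
METTL3
METTL14
WTAP
KIAA1429
RBM15
ZC3H13
FTO
ALKBH5
YTHDC1
YTHDC2
YTHDF1
YTHDF2
YTHDF3
HNRNPC
HNRNPA2B1
EIF3A
EIF3C
EIF3D
EIF3G
LRPPRC
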
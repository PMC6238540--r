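codon	w
AAA	0.83
AAC	0.931
AAG	0.955
AAT	0.766
ACA	0.722
ACC	0.803
ACG	0.159
ACT	0.528
AGA	0.548
AGC	0.366
AGG	0.405
AGT	0.308
ATA	0.437
ATC	0.629
ATG	0.677
ATT	0.629
CAA	0.564
CAC	0.847
CAG	0.611
CAT	0.267
CCA	0.994
CCC	0.591
CCG	0.372
CCT	0.97
CGA	0.904
CGC	0.669
CGG	0.797
CGT	0.875
CTA	0.507
CTC	0.225
CTG	0.933
CTT	0.384
GAA	0.916
GAC	0.3
GAG	0.763
GAT	0.588
GCA	0.915
GCC	0.217
GCG	0.312
GCT	0.819
GGA	0.528
GGC	0.676
GGG	0.249
GGT	0.221
GTA	0.685
GTC	0.244
GTG	0.269
GTT	0.301
TAA	0.407
TAC	0.397
TAG	0.549
TAT	0.559
TCA	0.459
TCC	0.793
TCG	0.16
TCT	0.965
TGA	0.479
TGC	0.567
TGG	0.669
TGT	0.605
TTA	0.201
TTC	0.854
TTG	0.751
TTT	0.733
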
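codon,per_1000
TTT,23.3
TTC,23.8
TTA,9.8
TTG,20.0
CTT,21.2
CTC,15.5
CTA,6.7
CTG,14.2
ATT,32.2
ATC,18.9
ATA,9.5
ATG,26.2
GTT,24.6
GTC,13.6
GTA,9.8
GTG,14.3
TCT,16.7
TCC,10.7
TCA,20.6
TCG,11.7
CCT,9.5
CCC,4.4
CCA,26.1
CCG,9.7
ACT,18.7
ACC,10.4
ACA,20.0
ACG,9.0
GCT,21.8
GCC,12.6
GCA,19.8
GCG,8.2
TAT,17.5
TAC,13.7
TAA,1.6
TAG,0.6
CAT,14.1
CAC,9.3
CAA,27.4
CAG,14.4
AAT,28.9
AAC,18.2
AAA,37.5
AAG,25.8
GAT,35.5
GAC,17.1
GAA,40.8
GAG,24.5
TGT,11.2
TGC,9.1
TGA,1.4
TGG,11.1
CGT,11.3
CGC,5.0
CGA,12.3
CGG,4.6
AGT,12.1
AGC,8.9
AGA,15.8
AGG,4.0
GGT,10.9
GGC,6.7
GGA,31.7
GGG,4.4
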
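>FOXL2_like
A  [   4   4  88  88  88   4  88  88 ]
C  [   4   4   4   4   4  88   4   4 ]
G  [  88   4   4   4   4   4   4   4 ]
T  [   4  88   4   4   4   4   4   4 ]
>DECOY_01_GATTCAA
A  [   4  89   4   4   4  89  89 ]
C  [   4   4   4   4  89   4   4 ]
G  [  89   4   4   4   4   4   4 ]
T  [   4   4  89  89   4   4   4 ]
>DECOY_02_TTATGAAGC
A  [   8   8  75   8   8  75  75   8   8 ]
C  [   8   8   8   8   8   8   8   8  75 ]
G  [   8   8   8   8  75   8   8  75   8 ]
T  [  75  75   8  75   8   8   8   8   8 ]
>DECOY_03_AACGGCTGAG
A  [  87  87   4   4   4   4   4   4  87   4 ]
C  [   4   4  87   4   4  87   4   4   4   4 ]
G  [   4   4   4  87  87   4   4  87   4  87 ]
T  [   4   4   4   4   4   4  87   4   4   4 ]
>DECOY_04_TGGGGAA
A  [   4   4   4   4   4  89  89 ]
C  [   4   4   4   4   4   4   4 ]
G  [   4  89  89  89  89   4   4 ]
T  [  89   4   4   4   4   4   4 ]
>DECOY_05_TTACGAG
A  [   5   5  84   5   5  84   5 ]
C  [   5   5   5  84   5   5   5 ]
G  [   5   5   5   5  84   5  84 ]
T  [  84  84   5   5   5   5   5 ]
>DECOY_06_CTCGTAAG
A  [   5   5   5   5   5  86  86   5 ]
C  [  86   5  86   5   5   5   5   5 ]
G  [   5   5   5  86   5   5   5  86 ]
T  [   5  86   5   5  86   5   5   5 ]
>DECOY_07_TCGCGCA
A  [   5   5   5   5   5   5  84 ]
C  [   5  84   5  84   5  84   5 ]
G  [   5   5  84   5  84   5   5 ]
T  [  84   5   5   5   5   5   5 ]
>DECOY_08_ATCAAGC
A  [  76   8   8  76  76   8   8 ]
C  [   8   8  76   8   8   8  76 ]
G  [   8   8   8   8   8  76   8 ]
T  [   8  76   8   8   8   8   8 ]
>DECOY_09_TGGCTGCC
A  [   7   7   7   7   7   7   7   7 ]
C  [   7   7   7  79   7   7  79  79 ]
G  [   7  79  79   7   7  79   7   7 ]
T  [  79   7   7   7  79   7   7   7 ]
>DECOY_10_GTTTGACCC
A  [   4   4   4   4   4  87   4   4   4 ]
C  [   4   4   4   4   4   4  87  87  87 ]
G  [  87   4   4   4  87   4   4   4   4 ]
T  [   4  87  87  87   4   4   4   4   4 ]
>DECOY_11_TAACCTTAGT
A  [   8  77  77   8   8   8   8  77   8   8 ]
C  [   8   8   8  77  77   8   8   8   8   8 ]
G  [   8   8   8   8   8   8   8   8  77   8 ]
T  [  77   8   8   8   8  77  77   8   8  77 ]
>DECOY_12_ATACGTGT
A  [  84   5  84   5   5   5   5   5 ]
C  [   5   5   5  84   5   5   5   5 ]
G  [   5   5   5   5  84   5  84   5 ]
T  [   5  84   5   5   5  84   5  84 ]
>DECOY_13_TGACAAACC
A  [   4   4  88   4  88  88  88   4   4 ]
C  [   4   4   4  88   4   4   4  88  88 ]
G  [   4  88   4   4   4   4   4   4   4 ]
T  [  88   4   4   4   4   4   4   4   4 ]
>DECOY_14_TTGTTGA
A  [   7   7   7   7   7   7  78 ]
C  [   7   7   7   7   7   7   7 ]
G  [   7   7  78   7   7  78   7 ]
T  [  78  78   7  78  78   7   7 ]
>DECOY_15_GCTAAAGGTG
A  [   4   4   4  89  89  89   4   4   4   4 ]
C  [   4  89   4   4   4   4   4   4   4   4 ]
G  [  89   4   4   4   4   4  89  89   4  89 ]
T  [   4   4  89   4   4   4   4   4  89   4 ]
>DECOY_16_ATAACTTCC
A  [  84   5  84  84   5   5   5   5   5 ]
C  [   5   5   5   5  84   5   5  84  84 ]
G  [   5   5   5   5   5   5   5   5   5 ]
T  [   5  84   5   5   5  84  84   5   5 ]
>DECOY_17_TGTCTTAG
A  [   7   7   7   7   7   7  80   7 ]
C  [   7   7   7  80   7   7   7   7 ]
G  [   7  80   7   7   7   7   7  80 ]
T  [  80   7  80   7  80  80   7   7 ]
>DECOY_18_GTTAGCAAT
A  [   5   5   5  84   5   5  84  84   5 ]
C  [   5   5   5   5   5  84   5   5   5 ]
G  [  84   5   5   5  84   5   5   5   5 ]
T  [   5  84  84   5   5   5   5   5  84 ]
>DECOY_19_TCATTGGCT
A  [   8   8  75   8   8   8   8   8   8 ]
C  [   8  75   8   8   8   8   8  75   8 ]
G  [   8   8   8   8   8  75  75   8   8 ]
T  [  75   8   8  75  75   8   8   8  75 ]
>DECOY_20_CCGAATGGC
A  [   8   8   8  77  77   8   8   8   8 ]
C  [  77  77   8   8   8   8   8   8  77 ]
G  [   8   8  77   8   8   8  77  77   8 ]
T  [   8   8   8   8   8  77   8   8   8 ]
>DECOY_21_CAGACAGGG
A  [   3  90   3  90   3  90   3   3   3 ]
C  [  90   3   3   3  90   3   3   3   3 ]
G  [   3   3  90   3   3   3  90  90  90 ]
T  [   3   3   3   3   3   3   3   3   3 ]
>DECOY_22_CCTGGAGCGC
A  [   6   6   6   6   6  83   6   6   6   6 ]
C  [  83  83   6   6   6   6   6  83   6  83 ]
G  [   6   6   6  83  83   6  83   6  83   6 ]
T  [   6   6  83   6   6   6   6   6   6   6 ]
>DECOY_23_AGCGTTATCA
A  [  82   6   6   6   6   6  82   6   6  82 ]
C  [   6   6  82   6   6   6   6   6  82   6 ]
G  [   6  82   6  82   6   6   6   6   6   6 ]
T  [   6   6   6   6  82  82   6  82   6   6 ]
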
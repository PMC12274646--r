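>IGKJ1*01 synthetic stand-in for the mouse kappa J1 reference allele
GTGGACGTTCGGTGGAGGCACCAAGCTGGAAATCAAAC
>IGKJ2*01 synthetic stand-in for the mouse kappa J2 reference allele
TGTACACGTTCGGATTGGGGACCAAGCTGGAAATAAAAC
>IGLJ1*01 synthetic stand-in for the mouse lambda J1 reference allele
CTGGGTGTTCGGTGGAGGAACCAAACTGACTGTCCTAG
>IGLJ2*01 synthetic stand-in for the mouse lambda J2 reference allele
TTATGTTTTCGGCGGTGGAACCAAGGTCACTGTCCTAG
>IGLJ3*01 synthetic stand-in for the mouse lambda J3 reference allele
TTTGTGTTCGGAGGTGGAACCAAACTGACTGTCCTAG
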
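>SsMIR156b-c family=miR156 arm=5p
UGACAGAAGAGAGUGAGCAC
>SsMIR159 family=miR159 arm=3p
UUUGGAUUGAAGGGAGCUCUG
>SsMIR167 family=miR167 arm=5p
UGAAGCUGCCAGCAUGAUCUG
>SsMIR168 family=miR168 arm=5p
UCGCUUGGUGCAGAUCGGGAC
>SsMIR169 family=miR169 arm=5p
UAGCCAAGGAUGACUUGCCGG
>SsMIR396 family=miR396 arm=5p
UUCCACAGCUUUCUUGAACUG
>SsMIR827 family=miR827 arm=3p
UUAGAUGACCAUCAGCAAACA
>SsMIR408a family=miR408 arm=3p
CUGCACUGCCUCUUCCCUGGC
>SsMIR408b family=miR408 arm=3p
CUGCACUGCCUCUUCCCUGGC
>SsMIR437a family=miR437 arm=3p
AAAGUUAGAGAAGUUUGACUU
>SsMIR437b family=miR437 arm=3p
AAAGUUAGACAAGUUUGACAU
>SsMIR437c family=miR437 arm=3p
AAAGUUAGAGAAGUCUGACUU
>SsMIR444a family=miR444 arm=3p
UGCAGUUGUUGCCUCAAGCUU
>SsMIR444b family=miR444 arm=3p
UGCAGUUGUUGCCUCAAGCUU
>SsMIR444c family=miR444 arm=3p
UGCAGUUGUUGUCUCAAGCUU
>SsMIR528 family=miR528 arm=5p
UGGAAGGGGCAUGCAGAGGAG
>SsMIR1128 family=miR1128 arm=5p
UACUACUCCCUCCGUCCCAAA
>SsMIR1432 family=miR1432 arm=5p
CUCAGGAAAGAUGACACCGAC
>SsMIR319 family=miR319 arm=3p
UUGGACUGAAGGGUGCUCCC
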
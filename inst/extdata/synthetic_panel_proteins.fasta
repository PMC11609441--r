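>MMP2 synthetic stand-in carrying quantotypic peptide AFQVWSDVTPLR
AFQVWSDVTPLRTGDLFTAVSELGHKNSAGEVTINAPWDSLYAK
>MMP9 synthetic stand-in
QLAEEYLYRFGNADGAACHFPFIFEGRMTPR
>ELNE synthetic stand-in (neutrophil elastase)
IVGGHEAQPHSRPYVAILQRLVNVVLGAHNVRMVR
>IL1B synthetic stand-in carrying quantotypic peptide IPVALGLK
IPVALGLKSDGAYLQAVEIWDKMDQAVK
>TNFA synthetic stand-in carrying quantotypic peptide VNLLSAIK
VNLLSAIKELTEAGQLFSSDRMLSAIK
>S100A8 synthetic stand-in
LLETECPQYIRALNSIIDVYHKMLTELEK
>S100A9 synthetic stand-in
VIEHIFEDLDTNADKQLSFEEFIVLVSRMTCK
>COL1A1 synthetic stand-in
GVQGPPGPAGPRGETGPAGPAGPVGPVGARMFSDVK
>FN1 synthetic stand-in (fibronectin)
SYTITGLQPGTDYKWLPSSSPVTGYRMNVR
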
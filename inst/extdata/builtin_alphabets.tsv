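# Built-in reduced amino-acid alphabets, one per line:
# NAME<TAB>cluster cluster ...
# Names follow the literature abbreviation plus the number of clusters.
UNIPROT20	A R N D C Q E G H I L K M F P S T W Y V
UNIPROT18	A R N D C Q EP G HL I K M F S T W Y V
HSDM17	A D KE R N T S Q Y F LIV M C W H G P
MMSEQS12	AST LM IV KR EQ ND FY C G H P W
WASS14	WM DI P C AV K T RE G L Y SH F NQ
SDM12	A D KER N TSQ YF LIVM C W H G P
GBMR7	DN AEFIKLMQRVWY CH T S G P
WWMJ5	CMFILVWY ATH GP DE SNQRK
GBMR4	ADKERNTSQ YFLIVMCWH G P
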
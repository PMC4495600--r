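protein_id	token	site_pos	effect	reported_type	peptide
P04637	Lys386Asn	386	removed	I-	STSRHKKLMFKTEGPDSD
P06748	Lys263Arg	263	removed	I-	ASIEKGGSLPKVEAKFINYVK
P35520	Lys211Arg	211	removed	I-	ESHVGVAWRLKNEIPNSHILD
Q13133	Lys434Asn	434	removed	I-	QVFALRLQDKKLPPLLSEIWD
Q9UK13	Lys423Ile	423	removed	I-	QQVHSGQKSFKCEECGKGFYT
P15408	Lys222Asn	222	removed	I-	GGGSVGAVVVKQEPLEEDSPS
Q13133	Lys328Gln	328	removed	I-	DFSYNREDFAKAGLQVEFINP
Q9C086	Lys168Asn	168	removed	I-	KGELDDNGDLKKEINERLLTA
Q16665	Lys477T	477	removed	I-	DPALNQEVALKLEPNPESLEL
P29590	Lys487Asn	487	removed	I-	RKCSQTQCPRKVIKMESEEGK
Q9NSC2	Lys1086Asn	1086	removed	I-	IPANSLSSLIKTEVNGFVHVS
P14316	Lys166Ile	166	removed	I-	PEYAVLTSTIKNEVDSTVNII
Q5VWQ0	Lys313Asn	313	removed	I-	GLNKESFRYLKDEQLCRLNLG
P36956	Lys123Gln	123	removed	I-	MPAFSPGPGIKEESVPLSILQ
Q14865	Lys629Asn	629	removed	I-	MADYIANCTVKVDQLGSDDIH
P60709	Lys68Gln	68	removed	I-	AQSKRGILTLKYPIEHGIVTN
Q9Y6U3	Lys299Gln	299	removed	I-	AAKQIFVWKGKDANPQERKAA
Q9Y2K1	Lys328Gln	328	removed	I-	RAAERKRIIIKMEPEDIPTDE
P40337	Lys171Asn	171	removed	I-	RCLQVVRSLVKPENYRRLDIV
Q8N2W9	Lys128Met	128	removed	I-	GLGRLPAKTLKPEVRLVKLPF
P62805	Lys13Ile	13	removed	I-	GRGKGGKGLGKGGAKRHRKVL
P62805	Lys13Asn	13	removed	I-	GRGKGGKGLGKGGAKRHRKVL
P37840	Lys96Arg	96	removed	I-	GSIAAATGFVKKDQLGKNEEG
P08069	Lys1150Arg	1150	removed	I-	NCMVAEDFTVKIGDFGMTRDI
P54132	Lys347Asn	347	removed	I-	TSKDLLSKPEKMSMQELNPET
Q13547	Lys476Gln	476	removed	I-	KEEKPEAKGVKEFEVKLA
Q08499	Lys387Asn	387	removed	I-	TNSSIPRFGVKTEQEDVLAKE
Q9UBT2	Lys257Asn	257	removed	I-	TGYDPVKLFTKLFKDDIRYLL
P54132	Lys344Asn	344	removed	I-	VLSTSKDLLSKPEKMSMQELN
P49137	Lys353Arg	353	removed	I-	KEDKERWEDVKEEMTSALATM
Q9P2D1	Lys1196Asn	1196	removed	I-	MLRRLKEDVEKNLAPKEETII
Q13426	Lys210Arg	210	removed	I-	NAAQEREKDIKQEGETAICSE
Q9UHP3	Lys141Thr	141	removed	I-	RVLEASIAENKACLKRTPTEV
Q13129	Lys1561Thr	1561	removed	I-	CMVQGCLSVVKLESSIVRHYK
Q9Y458	Lys63Asn	63	removed	I-	GKSEPLEKQPKTEPSTSASSG
P63165	Lys16Asn	16	removed	I-	AKPSTEDLGDKKEGEYIKLKV
Q9Y2W7	Lys90Gln	90	removed	I-	DQLQAQTKFTKKELQSLYRGF
Q16665	Lys391Arg	391	removed	I-	EDTSSLFDKLKKEPDALTLLA
P49792	Lys2725Gln	2725	removed	I-	EKKPTVEEKAKADTLKLPPTF
P14316	Lys137Gln	137	removed	I-	TEKEDKVKHIKQEPVESSLGL
Q15054	Lys433Gln	433	removed	I-	SVHRPPAMTVKKEPREERKGP
Q96JM2	Lys2482Asn	2482	removed	I-	DEAIGIDFSLKNETVAICVVT
O15151	Lys254Asn	254	removed	I-	SVSEQLGVGIKVEAADTEQTS
P05067	Lys670Asn	670	removed	I-	NIKTEEISEVKMDAEFRHDSG
Q9UBT2	Lys623Asn	623	removed	I-	KLDEKENLSAKRSRIEQKEEL
P63165	Lys7Gln	7	removed	I-	MSDQEAKPSTEDLGDKK
Q00613	Lys298Asn	298	removed	I-	PLSSSPLVRVKEEPPSPPQSP
Q9UHP3	Lys99Gln	99	removed	I-	TNVIDLTGDDKDDLQRAIALS
P35240	Lys76Arg	76	removed	I-	YTIKDTVAWLKMDKKVLDHDV
Q9UKV8	Lys402Arg	402	removed	I-	PYVREFGIMVKDEMTDVTGRV
P10276	Lys399Arg	399	removed	I-	AKGAERVITLKMEIPGSMPPL
P17544	Lys118Arg	118	removed	I-	SLPSTPDIKIKEEEPVEVDSS
P10276	Lys166Arg	166	removed	I-	ESVRNDRNKKKKEVPKPECSE
P10276	Lys171Arg	171	removed	I-	DRNKKKKEVPKPECSESYTLT
O60481	Lys248Arg	248	removed	I-	AFFRYMRQPIKQELSCKWIDE
Q9UKL3	Gln1792Lys	1792	created	I+	ANRPLKCIVEETYIDLTTESP
Q9C0J8	Leu240Lys	240	created	I+	DFLRCHEERILRGHGADVKCV
Q9C0J8	Thr255Lys	255	created	I+	ADVKCVDWHPTKGLVVSGSKD
P06748	Arg101Lys	101	created	I+	GFEITPPVVLRLKCGSGPVHI
P54253	Ser776Ala	772	removed	II-	IEPSKPAATRKRRWSAPESRK
Q00613	Ser303Ala	298	removed	II-	PLSSSPLVRVKEEPPSPPQSP
P02545	Gln203Gly	201	removed	II-	VDAENRLQTMKEELDFQKNIY
Q9UHP3	Ile92Ala	99	removed	II-	TNVIDLTGDDKDDLQRAIALS
Q53GS9	Lys6Arg	16	removed	II-	KRESRGSTRGKRESESRGSSG
O00257	Thr497Ala	494	retained	III	AGEPPSSLQVKPETPASAAVA
P04637	Phe385Ala	386	retained	III	STSRHKKLMFKTEGPDSD
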
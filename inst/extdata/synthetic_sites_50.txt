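Proteins	Gene names	Positions within proteins	Amino acid	Localization prob	Sequence window	Reverse	Potential contaminant	Intensity s1___1	Intensity s1___2	Intensity s1___3	Intensity s2___1	Intensity s2___2	Intensity s2___3
FIXPROT01	FIX01	29	S	0.911347932629287	APHMRNFSCDSVMMM			1257819	0	0	1751402.1	0	0
FIXPROT02	FIX02	424	Y	0.986987417973578	NALLEFAYTHSPDKV			1257819	0	0	1751402.1	0	0
FIXPROT03	FIX03	438	S	0.895395101401955	LSVIAMLSKNMEAEW			1257819	0	0	1751402.1	0	0
FIXPROT04	FIX04	64	T	0.920214842613786	PVTGIMWTITGMWQC			1257819	0	0	1751402.1	0	0
FIXPROT05	FIX05	319	S	0.916803836226463	HMLLRYLSDWTIAKC			1257819	0	0	1751402.1	0	0
FIXPROT06	FIX06	392	Y	0.833952400907874	AAVGSGYYPVQWDEE			1257819	0	0	1751402.1	0	0
FIXPROT07	FIX07	245	T	0.926703727431595	IAANEFTTICSGDSN			1257819	0	0	1751402.1	0	0
FIXPROT08	FIX08	281	Y	0.830109537914395	HEQRFCLYHHWHKEL			1257819	0	0	1751402.1	0	0
FIXPROT09	FIX09	432	T	0.800849806088954	IPSKMMTTFPNQPTR			1257819	0	0	1751402.1	0	0
FIXPROT10	FIX10	213	S	0.946470258105546	LMREIEASSDSAMQK			1257819	0	0	1751402.1	0	0
FIXPROT11	FIX11	268	Y	0.971630503125489	SNAHEQIYPMARSHA			1257819	0	0	1751402.1	0	0
FIXPROT12	FIX12	252	T	0.984982068985701	NIWMMMCTDDAPDPM			1257819	0	0	1751402.1	0	0
FIXPROT13	FIX13	126	S	0.784069550819695	DKFEHSRSFCICPNN			1257819	0	0	1751402.1	0	0
FIXPROT14	FIX14	235	S	0.927812693119049	SVGNERASWQKDRHE			1257819	0	0	1751402.1	0	0
FIXPROT15	FIX15	377	T	0.914676324743777	WYWWNWKTHRQALDH			1257819	0	0	1751402.1	0	0
FIXPROT16	FIX16	143	Y	0.857315681278706	PPCYEGWYMHGINRT			1257819	0	0	1751402.1	0	0
FIXPROT17	FIX17	186	T	0.777612453140318	KHFWSVVTSAFGQNR			1257819	0	0	1751402.1	0	0
FIXPROT18	FIX18	234	S	0.882176779191941	PHQAYEQSQNQHMKG			1257819	0	0	1751402.1	0	0
FIXPROT19	FIX19	329	T	0.777870103511959	PLEDFRTTAHIQPYP			1257819	0	0	1751402.1	0	0
FIXPROT20	FIX20	266	S	0.959823288731277	LFLPQSLSCTVDTLT			1257819	0	0	1751402.1	0	0
FIXPROT21	FIX21	256	Y	0.98743156792596	GCLHIKAYCNEDATG			1257819	0	0	1751402.1	0	0
FIXPROT22	FIX22	376	S	0.922007024101913	TITFEAISQHCSRYQ			1257819	0	0	1751402.1	0	0
FIXPROT23	FIX23	322	T	0.877627368308604	NREKMAVTCYVFPWW			1257819	0	0	1751402.1	0	0
FIXPROT24	FIX24	278	Y	0.847408742960542	YYCKKLEYKNGLPFN			1257819	0	0	1751402.1	0	0
FIXPROT25	FIX25	81	S	0.990184191353619	IVFSKEESEITRQGF			1257819	0	0	1751402.1	0	0
FIXPROT26	FIX26	338	S	0.797795225046575	NTKGAECSHKTMIPP			1257819	0	0	1751402.1	0	0
FIXPROT27	FIX27	291	T	0.9005865826644	CAHFETSTKHTEFHS			1257819	0	0	1751402.1	0	0
FIXPROT28	FIX28	263	Y	0.925109746940434	GRVDYTEYKWKNSWN			1257819	0	0	1751402.1	0	0
FIXPROT29	FIX29	416	Y	0.812478894647211	HILPAGHYWKIFIYW			1257819	0	0	1751402.1	0	0
FIXPROT30	FIX30	160	S	0.75	KFMMIVCSEANDKKM			1257819	0	0	1751402.1	0	0
FIXPROT31	FIX31	34	Y	0.214836173057556	QHWALRIYHANPKRF			1257819	0	0	1751402.1	0	0
FIXPROT32	FIX32	267	T	0.310591835379601	GKQKWFLTHCHLRQL			1257819	0	0	1751402.1	0	0
FIXPROT33	FIX33	179	T	0.733550378382206	SFGIYDKTRHTSNNL			1257819	0	0	1751402.1	0	0
FIXPROT34	FIX34	274	Y	0.655803599655628	EASYRAQYVCRSSLL			1257819	0	0	1751402.1	0	0
FIXPROT35	FIX35	452	Y	0.716717295497656	HWVLDVKYYHADHGI			1257819	0	0	1751402.1	0	0
FIXPROT36	FIX36	342	S	0.384650186896324	IQIYGYCSHVPQRNF			1257819	0	0	1751402.1	0	0
FIXPROT37	FIX37	458	Y	0.35793221950531	IPCCKNYYAHSFIIE			1257819	0	0	1751402.1	0	0
FIXPROT38	FIX38	168	S	0.582322360128164	HKWVYKCSVLQPKGT			1257819	0	0	1751402.1	0	0
FIXPROT39	FIX39	368	S	0.676068968772888	YWYPSMFSQGPKFPV			1257819	0	0	1751402.1	0	0
FIXPROT40	FIX40	40	Y	0.462817700505257	KRYATPWYKKIWVRT			1257819	0	0	1751402.1	0	0
FIXPROT41	FIX41	194	S	0.387644270509481	TCSRGVNSNGCIPLI			1257819	0	0	1751402.1	0	0
FIXPROT42	FIX42	373	T	0.7499	HQVFDWNTWDIDMGN			1257819	0	0	1751402.1	0	0
FIXPROT43	FIX43	148	S	0.875058104936034	IAGNVIESMNKIWYF	+		1257819	0	0	1751402.1	0	0
FIXPROT44	FIX44	20	Y	0.866493021743372	ITHERWIYVIRSQKT	+		1257819	0	0	1751402.1	0	0
FIXPROT45	FIX45	436	Y	0.803305512340739	KVMYRHTYIGFGPLP	+		1257819	0	0	1751402.1	0	0
FIXPROT46	FIX46	38	S	0.864945741463453	SDRVIHESEFWEAET	+		1257819	0	0	1751402.1	0	0
FIXPROT47	FIX47	391	T	0.841628682008013	QHSGQFETFFPRFCD		+	1257819	0	0	1751402.1	0	0
FIXPROT48	FIX48	388	Y	0.962993656983599	CEFVYPLYGHNLTAL		+	1257819	0	0	1751402.1	0	0
FIXPROT49	FIX49	337	Y	0.987760943220928	YARVPRCYADHVMMV		+	1257819	0	0	1751402.1	0	0
FIXPROT50	FIX50	425	Y	0.987410418316722	EHGFQNDYQNYGSSF		+	1257819	0	0	1751402.1	0	0
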
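# Empirically evaluated degenerate PCR primer pairs (published set), with
# the printed degree-of-degeneration values for cross-checking.
id	forward	d_forward	reverse	d_reverse	total_d
3683_01_A	GCYATYTTCGAYTTYGAYAG	32	AAVGTRAAKGATTCGTTGTA	12	384
4652_02_A	ATGATGTDGARTTTATMATACARAC	24	CWACRCTWATTTCTCTWTCAAC	16	384
4747_02_A	TTCTACGGBATGATCTTYAG	6	ACCTBGACATRATCTTVGGC	18	108
5119_01_A	GGDATYGTMGARGAGAGYGT	48	TYTTCATYTTRTCCATGTGYTC	16	768
5257_01_A	MACVAATAARTAYGGHTGYAGA	144	TAATTGGTCTARRTTGAARCT	8	1152
5592_01_A	AAYTRAATAAAGACTGGAAAGAAGA	4	GTYARATCCATYCCRTGATC	16	64
5768_01_A	ACDGTHAARGTDTGGAATGC	54	GCWACCCAAATRCWAGWTTG	16	864
6917_01_A	ATGCCVTTCTACACRGTCTA	6	CYTCGCTYTTCTTCTGCATRTC	8	48
7036_02_A	TTTGTCWGYGKGTGCCTTGT	8	TTCATRGTWGCTTCRGTATCNGT	32	256
7229_02_A	TGCYTGATHCTSTTCTTCGT	12	TRTGRAAYCTRTGRAAGATGCA	32	384
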
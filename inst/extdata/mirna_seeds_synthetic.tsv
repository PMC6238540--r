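mirna_id	sequence	expression_rank
syn-mir-01	CCUAUAAUCUACCCGCAGAGGA	1
syn-mir-02	CAGUGGCCGGGCUACGCUCGCA	2
syn-mir-03	UUGUUAUGUAAAUCAUCGAUCU	3
syn-mir-04	CACGAAUGUCCAUCCCACAGUG	4
syn-mir-05	UGUCGGGUGGGUGUUGUACUAA	5
syn-mir-06	AUCUGGCUAGAAUAGCAGACUC	6
syn-mir-07	AGCUCUGUGAAGUGAUUUAGUC	7
syn-mir-08	CAGAUAUUCUCGGAGAUCUGAG	8
syn-mir-09	CAUCAACGCGUGACAAACGUGA	9
syn-mir-10	CCCGUCAACGAUUAGUCUAUCU	10
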
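site_label	class	chrom	start	end	forward_primer	reverse_primer
pos1	positive	chr1	44915566	44915581	AAACCACTCTCCCCCAAAGC	TTTGAAGTTCCGGAGCGGTT
pos2	positive	chr15	30383190	30383333	CTTAAAAGCAGGCTCCCTCG	CTCCACACTTCAAAAGGAGAGAAAG
pos3	positive	chr4	129251719	129251895	ATTTCAAACAAACTCCCCGC	TGTGGAATTAGTTTGGGGCTCTGAT
pos4	positive	chr5	74953049	74953184	AAGTGACCCTTTGTTCTCTGTCC	AAAGAATGGGCCGGGATG
neg1	negative	chr14	111679747	111681304	ACAGCTTCACTTCCTTGCCA	TTTGAATGAGGGAAGTCAGCT
neg2	negative	chr7	10494816	10495738	GCCCTTAGAACCGCTCCTTT	TCCAGATCGTGTGCAAGACC
neg3	negative	chr1	99772205	99772613	ACTATTGGTGGAGCTGTGCG	TGCTTGCCTTTCTTGCTTGC
neg4	negative	chr3	111370868	111371261	AAGCAGCAAGAGGGAACACT	TGCATGCCACAGAATACTTTTAA
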
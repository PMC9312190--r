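accession	start	end	length	x	pValue	sequence
O75400	65	121	57	19	1.79e-13	PMGMHPMGQRANMPPVPHGMMPQMMPPMGGPPMGQMPGMMSSVMPGMMMSHMSQASM
Q8WYB5	1961	2068	108	21	4.53e-13	MQRGMNMSVNLMPAPAYNVNSVNMNMNTLNAMNGYSMSQPMMNSGYHSNHGYMNQTPQYPMQMQMGMMGTQPYAQQPMQTPPHGNMMYTAPGHHGYMNTGMSKQSLNG
Q92794	1894	1977	84	18	5.74e-12	QRGMNMGVNLMPTPAYNVNSMNMNTLNAMNSYRMTQPMMNSSYHSNPAYMNQTAQYPMQMQMGMMGSQAYTQQPMQPNPHGNMM
Q96JP2	820	847	28	8	6.25e-9	PMVYPGMIQMPAYQPGMVPAPMPMMPAM
Q9UMZ2	37	94	58	12	9.29e-9	PPQAGLMPMQQQGFPMVSVMQPNMQGIMGMNYSSQMSQGPIAMQAGIPMGPMPAAGMP
Q14677	549	591	43	14	1.72e-8	MPMSMPNVMTGTMGMAPLGNTPMMNQSMMGMNMNIGMSAAGMG
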
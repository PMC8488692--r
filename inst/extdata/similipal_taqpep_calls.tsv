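sample_id	individual	method	call	replicate
STR18F-01	INDV-1	sanger	x/x	0
STR18F-01	INDV-1	ngs	+/+	0
STR18F-01	INDV-1	aspcr	+/+	0
STR18F-25	INDV-1	sanger	+/+	0
STR18F-25	INDV-1	ngs	x/x	0
STR18F-25	INDV-1	aspcr	+/+	0
STR18F-75	INDV-1	sanger	+/+	0
STR18F-75	INDV-1	ngs	+/+	0
STR18F-75	INDV-1	aspcr	+/+	0
SIM19F-14	INDV-1	sanger	+/+	0
SIM19F-14	INDV-1	ngs	+/+	0
SIM19F-14	INDV-1	aspcr	+/+	0
STR18-02	INDV-2	sanger	+/m	0
STR18-02	INDV-2	ngs	x/x	0
STR18-02	INDV-2	aspcr	+/m	0
STR18-27	INDV-2	sanger	+/m	0
STR18-27	INDV-2	ngs	x/x	0
STR18-27	INDV-2	aspcr	+/m	0
STR18-49	INDV-2	sanger	+/m	0
STR18-49	INDV-2	ngs	x/x	0
STR18-49	INDV-2	aspcr	+/m	0
SIM19-09	INDV-2	sanger	x/x	0
SIM19-09	INDV-2	ngs	+/m	0
SIM19-09	INDV-2	aspcr	+/m	0
SIM19-29	INDV-2	sanger	+/m	0
SIM19-29	INDV-2	ngs	+/m	0
SIM19-29	INDV-2	aspcr	+/m	0
STRF18-04	INDV-3	sanger	+/m	0
STRF18-04	INDV-3	ngs	x/x	0
STRF18-04	INDV-3	aspcr	+/m	0
STRF18-19	INDV-3	sanger	+/m	0
STRF18-19	INDV-3	ngs	+/m	0
STRF18-19	INDV-3	aspcr	+/m	0
STRF18-21	INDV-3	sanger	+/m	0
STRF18-21	INDV-3	ngs	x/x	0
STRF18-21	INDV-3	aspcr	+/m	0
STRF18-43	INDV-3	sanger	+/m	0
STRF18-43	INDV-3	ngs	+/m	0
STRF18-43	INDV-3	aspcr	+/m	0
STRF18-56	INDV-3	sanger	+/m	0
STRF18-56	INDV-3	ngs	x/x	0
STRF18-56	INDV-3	aspcr	+/m	0
STRF18-57	INDV-3	sanger	x/x	0
STRF18-57	INDV-3	ngs	+/m	0
STRF18-57	INDV-3	aspcr	+/m	0
STRF18-58	INDV-3	sanger	x/x	0
STRF18-58	INDV-3	ngs	x/x	0
STRF18-58	INDV-3	aspcr	+/m	0
STRF18-81	INDV-3	sanger	+/+	0
STRF18-81	INDV-3	ngs	x/x	0
STRF18-81	INDV-3	aspcr	+/m	0
STRF18-81	INDV-3	aspcr	+/m	1
STRF18-81	INDV-3	aspcr	+/m	2
STRF18-81	INDV-3	aspcr	+/m	3
STRF18-92	INDV-3	sanger	+/m	0
STRF18-92	INDV-3	ngs	+/m	0
STRF18-92	INDV-3	aspcr	+/m	0
STRF18-07	INDV-4	sanger	m/m	0
STRF18-07	INDV-4	ngs	m/m	0
STRF18-07	INDV-4	aspcr	m/m	0
STRF18-20	INDV-4	sanger	m/m	0
STRF18-20	INDV-4	ngs	m/m	0
STRF18-20	INDV-4	aspcr	m/m	0
STRF18-26	INDV-4	sanger	m/m	0
STRF18-26	INDV-4	ngs	m/m	0
STRF18-26	INDV-4	aspcr	m/m	0
STRF18-41	INDV-4	sanger	m/m	0
STRF18-41	INDV-4	ngs	m/m	0
STRF18-41	INDV-4	aspcr	m/m	0
STRF18-46	INDV-4	sanger	x/x	0
STRF18-46	INDV-4	ngs	m/m	0
STRF18-46	INDV-4	aspcr	m/m	0
STRF18-61	INDV-4	sanger	m/m	0
STRF18-61	INDV-4	ngs	m/m	0
STRF18-61	INDV-4	aspcr	m/m	0
STRF18-84	INDV-4	sanger	m/m	0
STRF18-84	INDV-4	ngs	x/x	0
STRF18-84	INDV-4	aspcr	m/m	0
STRF18-09	INDV-5	sanger	x/x	0
STRF18-09	INDV-5	ngs	+/m	0
STRF18-09	INDV-5	aspcr	m/m	0
STRF18-09	INDV-5	aspcr	m/m	1
STRF18-09	INDV-5	aspcr	m/m	2
STRF18-09	INDV-5	aspcr	m/m	3
SIMF19-01	INDV-5	sanger	m/m	0
SIMF19-01	INDV-5	ngs	m/m	0
SIMF19-01	INDV-5	aspcr	m/m	0
STRF18-10	INDV-6	sanger	x/x	0
STRF18-10	INDV-6	ngs	x/x	0
STRF18-10	INDV-6	aspcr	m/m	0
STRF18-11	INDV-6	sanger	+/m	0
STRF18-11	INDV-6	ngs	+/m	0
STRF18-11	INDV-6	aspcr	+/m	0
STRF18-50	INDV-6	sanger	+/m	0
STRF18-50	INDV-6	ngs	+/m	0
STRF18-50	INDV-6	aspcr	+/m	0
STRF18-94	INDV-6	sanger	+/+	0
STRF18-94	INDV-6	ngs	x/x	0
STRF18-94	INDV-6	aspcr	+/m	0
STRF18-94	INDV-6	aspcr	+/m	1
STRF18-94	INDV-6	aspcr	+/m	2
STRF18-94	INDV-6	aspcr	+/m	3
STRF18-08	INDV-7	sanger	x/x	0
STRF18-08	INDV-7	ngs	x/x	0
STRF18-08	INDV-7	aspcr	m/m	0
STRF18-59	INDV-8	sanger	+/+	0
STRF18-59	INDV-8	ngs	x/x	0
STRF18-59	INDV-8	aspcr	+/+	0
STRF18-62	INDV-9	sanger	m/m	0
STRF18-62	INDV-9	ngs	m/m	0
STRF18-62	INDV-9	aspcr	x/x	0
STRF18-85	INDV-10	sanger	x/x	0
STRF18-85	INDV-10	ngs	x/x	0
STRF18-85	INDV-10	aspcr	+/m	0
SIM18T-103	INDV-11	sanger	+/m	0
SIM18T-103	INDV-11	ngs	x/x	0
SIM18T-103	INDV-11	aspcr	x/x	0
SIM19-08	INDV-12	sanger	+/m	0
SIM19-08	INDV-12	ngs	+/m	0
SIM19-08	INDV-12	aspcr	+/m	0
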
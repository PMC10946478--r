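##fileformat=VCFv4.2
##source=demsel
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	p1_01	p1_02	p1_03	p1_04	p2_01	p2_02	p2_03	p2_04
locus_00001	1	.	A	T	.	PASS	.	GT:DP	0/0:24	0/1:15	0/1:13	0/1:5	0/0:25	0/1:23	0/1:13	1/1:20
locus_00002	1	.	A	T	.	PASS	.	GT:DP	0/0:21	0/0:9	0/0:30	0/0:21	0/0:21	0/0:20	0/1:30	0/0:43
locus_00003	1	.	A	T	.	PASS	.	GT:DP	0/0:18	0/1:35	1/1:13	0/0:27	0/0:23	0/0:46	0/0:13	0/0:20
locus_00004	1	.	A	T	.	PASS	.	GT:DP	0/0:17	0/0:14	0/0:29	0/0:18	0/1:40	0/0:26	0/1:16	0/1:22
locus_00005	1	.	A	T	.	PASS	.	GT:DP	0/0:16	0/0:6	./.:0	0/0:17	0/1:26	0/1:22	0/1:33	0/1:22
locus_00006	1	.	A	T	.	PASS	.	GT:DP	0/0:11	0/0:19	0/0:20	0/0:19	0/0:14	./.:0	0/1:36	0/0:8
locus_00007	1	.	A	T	.	PASS	.	GT:DP	0/0:4	0/0:22	0/0:30	0/0:11	0/0:14	./.:0	0/0:11	0/1:22
locus_00008	1	.	A	T	.	PASS	.	GT:DP	0/0:33	0/0:10	0/0:32	0/0:23	0/1:11	0/0:24	0/0:11	1/1:27
locus_00009	1	.	A	T	.	PASS	.	GT:DP	0/0:22	0/0:18	0/0:31	0/0:26	0/0:22	./.:0	1/1:25	0/1:9
locus_00010	1	.	A	T	.	PASS	.	GT:DP	0/1:4	./.:0	./.:0	0/0:30	0/0:24	0/0:42	0/1:22	0/0:44
locus_00011	1	.	A	T	.	PASS	.	GT:DP	0/0:16	0/1:10	0/0:18	0/0:15	0/0:23	./.:0	0/1:15	0/1:8
locus_00012	1	.	A	T	.	PASS	.	GT:DP	0/1:21	0/0:3	./.:0	0/0:17	0/0:20	0/0:21	0/0:25	0/1:20
locus_00013	1	.	A	T	.	PASS	.	GT:DP	0/0:13	0/1:18	0/1:41	0/1:5	0/0:50	0/0:42	0/0:18	0/0:34
locus_00014	1	.	A	T	.	PASS	.	GT:DP	0/0:40	0/0:21	0/1:34	0/0:18	0/1:43	0/1:18	0/1:6	0/1:5
locus_00015	1	.	A	T	.	PASS	.	GT:DP	0/0:24	0/0:14	0/0:8	0/0:14	0/0:8	0/0:12	0/0:8	1/1:23
locus_00016	1	.	A	T	.	PASS	.	GT:DP	0/0:18	0/0:9	0/0:8	0/0:25	0/0:28	0/1:26	0/0:29	0/0:45
locus_00017	1	.	A	T	.	PASS	.	GT:DP	0/0:26	0/0:23	0/1:19	0/1:19	0/1:39	0/0:11	0/1:19	1/1:45
locus_00018	1	.	A	T	.	PASS	.	GT:DP	0/0:11	0/0:16	0/0:14	0/0:17	1/1:6	./.:0	0/1:49	1/1:17
locus_00019	1	.	A	T	.	PASS	.	GT:DP	0/0:8	0/0:9	0/0:25	0/0:24	0/0:34	0/1:25	./.:0	0/0:25
locus_00020	1	.	A	T	.	PASS	.	GT:DP	0/0:26	0/0:31	0/0:17	0/1:23	0/0:13	0/0:29	0/0:25	0/0:17
locus_00021	1	.	A	T	.	PASS	.	GT:DP	0/0:28	0/0:19	0/0:11	0/0:35	0/0:31	./.:0	0/0:18	0/0:15
locus_00022	1	.	A	T	.	PASS	.	GT:DP	0/0:41	0/0:24	0/0:13	0/0:13	1/1:5	0/1:16	1/1:29	0/1:20
locus_00023	1	.	A	T	.	PASS	.	GT:DP	0/0:16	0/0:21	0/0:16	0/0:15	0/1:12	0/0:21	0/0:32	0/0:62
locus_00024	1	.	A	T	.	PASS	.	GT:DP	0/0:19	0/0:57	0/0:19	0/0:21	0/0:16	0/0:11	0/0:4	0/1:17
locus_00025	1	.	A	T	.	PASS	.	GT:DP	0/0:24	0/0:10	0/0:55	0/0:6	0/0:18	0/0:39	0/0:31	0/1:18
locus_00026	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:28	0/1:21	0/0:15	0/0:20	1/1:21	0/1:28	./.:0
locus_00027	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:30	0/0:16	0/0:14	./.:0	0/0:34	0/0:12	0/1:33
locus_00028	1	.	A	T	.	PASS	.	GT:DP	0/0:18	0/0:20	0/1:22	0/0:18	0/0:14	0/0:45	0/0:19	0/0:12
locus_00029	1	.	A	T	.	PASS	.	GT:DP	0/0:13	./.:0	0/0:9	0/0:21	0/0:21	0/1:25	0/0:7	./.:0
locus_00030	1	.	A	T	.	PASS	.	GT:DP	0/0:19	0/0:19	0/0:26	0/0:14	0/0:21	0/0:16	0/1:26	./.:0
locus_00031	1	.	A	T	.	PASS	.	GT:DP	0/1:19	0/1:19	0/1:19	./.:0	0/0:15	0/0:4	0/0:6	0/0:10
locus_00032	1	.	A	T	.	PASS	.	GT:DP	0/0:7	0/0:19	0/1:19	0/0:19	0/0:18	0/0:18	./.:0	0/0:40
locus_00033	1	.	A	T	.	PASS	.	GT:DP	0/0:17	1/1:20	./.:0	0/0:22	0/1:14	1/1:26	0/1:17	0/1:23
locus_00034	1	.	A	T	.	PASS	.	GT:DP	0/0:9	0/0:10	0/0:15	0/0:24	1/1:24	0/1:5	0/1:34	0/1:25
locus_00035	1	.	A	T	.	PASS	.	GT:DP	0/0:15	0/0:31	0/0:22	0/1:4	./.:0	./.:0	0/0:25	0/0:34
locus_00036	1	.	A	T	.	PASS	.	GT:DP	0/0:46	0/0:32	0/0:22	0/0:18	0/0:24	./.:0	0/1:11	0/0:21
locus_00037	1	.	A	T	.	PASS	.	GT:DP	0/0:32	0/0:21	0/0:20	0/0:11	0/0:11	./.:0	0/1:2	0/0:23
locus_00038	1	.	A	T	.	PASS	.	GT:DP	0/1:21	0/1:12	0/0:22	0/1:1	0/0:6	./.:0	0/0:15	0/0:15
locus_00039	1	.	A	T	.	PASS	.	GT:DP	0/0:13	0/0:6	./.:0	0/0:13	0/1:35	0/1:34	0/1:30	0/0:17
locus_00040	1	.	A	T	.	PASS	.	GT:DP	0/0:4	0/0:18	0/0:12	0/0:23	1/1:18	0/1:15	0/1:18	0/1:6
locus_00041	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:22	0/0:6	0/0:8	0/0:28	0/0:40	0/0:26	0/1:18
locus_00042	1	.	A	T	.	PASS	.	GT:DP	0/0:17	0/1:20	0/1:19	0/0:37	0/0:18	0/0:15	0/0:14	0/0:21
locus_00043	1	.	A	T	.	PASS	.	GT:DP	0/0:18	0/0:20	0/0:25	0/0:20	0/0:18	0/0:14	0/0:19	0/1:21
locus_00044	1	.	A	T	.	PASS	.	GT:DP	0/0:32	0/1:22	0/0:8	0/1:18	./.:0	0/0:41	0/0:31	0/0:9
locus_00045	1	.	A	T	.	PASS	.	GT:DP	0/0:15	0/0:29	0/0:26	0/0:32	0/0:22	0/0:23	0/0:4	0/1:32
locus_00046	1	.	A	T	.	PASS	.	GT:DP	0/1:25	0/0:14	0/0:33	0/0:18	0/0:34	1/1:22	0/1:29	0/1:37
locus_00047	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:7	0/0:14	0/0:11	0/0:24	0/1:46	0/0:10	0/1:12
locus_00048	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:13	0/1:21	0/0:8	0/0:22	0/0:39	0/0:29	0/0:30
locus_00049	1	.	A	T	.	PASS	.	GT:DP	0/0:34	0/0:14	0/0:28	0/0:20	0/1:31	0/0:20	1/1:13	0/0:16
locus_00050	1	.	A	T	.	PASS	.	GT:DP	0/1:22	0/0:21	0/1:21	0/0:21	0/0:30	0/1:6	./.:0	0/1:10
locus_00051	1	.	A	T	.	PASS	.	GT:DP	0/0:18	0/0:35	0/1:9	0/0:31	0/0:29	0/0:25	0/0:39	0/0:37
locus_00052	1	.	A	T	.	PASS	.	GT:DP	0/0:11	0/0:16	./.:0	0/0:10	0/0:11	1/1:47	0/0:23	0/0:18
locus_00053	1	.	A	T	.	PASS	.	GT:DP	1/1:19	0/1:18	0/0:12	0/0:20	0/0:21	0/1:10	0/1:7	0/0:22
locus_00054	1	.	A	T	.	PASS	.	GT:DP	0/0:16	0/0:9	0/0:11	0/1:10	0/0:12	0/0:12	0/0:34	0/0:28
locus_00055	1	.	A	T	.	PASS	.	GT:DP	./.:0	0/0:12	0/0:17	0/0:21	0/0:21	0/1:17	0/0:23	./.:0
locus_00056	1	.	A	T	.	PASS	.	GT:DP	0/0:21	0/0:13	0/0:24	0/0:30	0/1:17	0/0:25	./.:0	0/0:18
locus_00057	1	.	A	T	.	PASS	.	GT:DP	0/0:20	0/0:40	0/1:25	0/0:9	0/0:31	0/0:23	0/0:14	0/0:28
locus_00058	1	.	A	T	.	PASS	.	GT:DP	1/1:21	0/1:28	0/1:12	1/1:15	0/0:4	0/0:12	0/1:11	0/0:20
locus_00059	1	.	A	T	.	PASS	.	GT:DP	0/0:15	0/0:25	0/0:36	0/0:27	0/0:12	0/1:5	0/0:37	0/0:19
locus_00060	1	.	A	T	.	PASS	.	GT:DP	0/0:2	0/1:25	0/0:38	0/0:17	0/0:11	0/0:12	0/0:18	0/0:15
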
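chrom	start	end	hotspot_id	category
1	87985753	89572574	HS016	gain
1	189842354	190700739	HS023	gain
2	61646411	63745771	HS065	loss
2	216021113	216917432	HS014	gain
3	19690012	22160755	HS064	loss
3	70193433	70807782	HS058	loss
3	184320565	185564948	HS003	gain
3	186613901	189010449	HS051	loss
4	44256789	45285875	HS027	gain
4	165397933	167806457	HS061	loss
5	105831387	106833908	HS024	gain
5	109984071	111765196	HS063	loss
6	62647138	65607133	HS050	loss
7	16841221	18292916	HS045	gain
7	19420772	21399628	HS011	gain
7	90597508	91584574	HS019	gain
7	121233821	121782011	HS012	gain
7	124853213	125257505	HS033	gain
7	144979179	146276653	HS028	gain
7	154795015	155618773	HS015	gain
8	40021906	42889991	HS017	gain
8	50776032	52543287	HS040	gain
8	96040363	98196223	HS002	gain
9	15339675	16319772	HS048	gain
9	46995388	48362160	HS035	gain
9	76806118	79270381	HS046	gain
9	103061525	104176959	HS009	gain
9	123566967	126457744	HS054	loss
9	126120358	126771577	HS021	gain
9	126206674	126412596	HS057	loss
10	18769663	20148040	HS032	gain
10	39910037	41669923	HS008	gain
10	57811219	59695915	HS039	gain
10	97872311	98396663	HS060	loss
10	108590164	110945623	HS007	gain
11	129981288	130295298	HS038	gain
13	8225993	10908158	HS031	gain
13	29504258	31248058	HS042	gain
13	63756698	64770883	HS049	gain
13	90631539	93592578	HS037	gain
13	97676051	98994056	HS055	loss
14	21927277	23687721	HS068	loss
14	43683230	45186516	HS043	gain
14	100486735	101834399	HS056	loss
15	16980765	19391267	HS018	gain
15	20434913	22559870	HS053	loss
16	59092093	60228141	HS047	gain
17	10804850	11334334	HS044	gain
17	51278571	52673734	HS022	gain
17	80036091	80860795	HS013	gain
18	19148024	20717743	HS036	gain
18	42262630	43711571	HS052	loss
18	72577695	74466144	HS030	gain
19	28255720	31131262	HS005	gain
20	24657317	27356602	HS025	gain
20	24731752	25752449	HS034	gain
20	27820914	29999431	HS041	gain
20	28865308	29546156	HS029	gain
20	31111631	33409320	HS062	loss
20	31615958	33421630	HS004	gain
20	34283058	36842677	HS006	gain
20	42636698	43415921	HS059	loss
20	42826235	43629275	HS010	gain
21	3090589	5056758	HS067	loss
21	38051573	39628945	HS001	gain
21	38571944	41496223	HS066	loss
22	26688088	29415880	HS026	gain
22	46481031	48688654	HS020	gain
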
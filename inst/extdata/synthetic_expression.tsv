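Hugo_Symbol	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012	S013	S014	S015	S016	S017	S018	S019	S020	S021	S022	S023	S024
G001	1.1554578765768768	0.7380986245072094	-0.19375834036419876	2.759682723973795	-0.1728250818838315	3.6851657218905403	-0.11450115578720788	2.382384277502837	4.1748752560555715	-2.5357321225625693	-0.5090025449364581	-0.2434133207495976	6.6383880061163145	4.958313744787647	0.6272313876015811	1.0215754407269309	7.887508210942766	4.917442785439627	2.2250434107452195	5.163411996983249	7.695002106607408	8.937468887949903	4.691357425322693	5.007579323166507
G002	-1.2815142461326692	0.7314155047278823	-0.6993196362858912	1.4988697283548171	0.6226865817970889	2.4186590181635097	-0.6386967051934118	1.4031588924349876	-0.08337379038202072	-1.7348172059167084	-1.025783081062994	-2.4518343199224617	4.0796903425526585	3.604092781294869	1.3960947814527418	2.6402564424404558	3.8113541843962984	2.050283710598667	2.781943097407623	2.6883390181750095	5.858897772256691	4.500801326546515	3.941493043673833	3.7361760756245004
G003	-0.7658754768467788	1.5396161158385835	0.628165796123488	0.0877035758638581	0.2702129537176265	0.6637213575134331	0.0877741602988014	-2.9244965708203576	0.2783542083731593	-0.35881862007009485	0.1809855823617432	0.5684899044902555	1.367658653011962	-0.7106244966998774	1.272691885286562	0.3281513911190961	1.0147063536483731	0.899627965017967	0.7043575892185059	-1.0192134797312713	-0.08811955906781646	0.6092288156897098	-0.9316711868106671	-0.5303886494092562
G004	0.5676816326686883	0.7505741632099026	0.45313929239130246	-0.8654767054521022	-1.0745769012609585	1.4780398651317124	0.25201057724560977	0.08641341881274786	-0.1181259165727075	-1.1669581139533522	0.5979715878736407	-0.21216358901073357	2.752679713141118	3.8432046915333156	3.7341884292240124	4.291460972846168	2.4659868237572407	3.5666924654995875	4.290478106251441	1.8459155221249652	2.090182577251076	1.8254458333856614	1.5054753614620886	3.0093977010046657
G005	0.6382346666080695	1.1734425042469792	1.0208082239089546	-0.9802178237181233	1.806119706551185	-0.6514927694298872	0.10309572185575627	-0.41257892152492814	-0.11954623762766044	0.1838801602229578	0.11643011180967104	-0.024517497611549675	3.0368441250360823	2.456937755152881	2.438586290435574	1.308216939910018	2.5576764569830246	2.4303464276639977	5.571219112835431	1.600347912095649	3.0653588091457014	1.4718529020558577	1.4945107914377826	3.053092676596333
G006	-0.5325569472016497	0.2800814893117505	-0.4924360568640116	0.454249370996109	-2.044275510853061	0.2105972165520198	0.13167713894655614	1.4643882408087938	1.1127037630023662	-0.968274428904266	0.9027800735240538	1.3139043859617048	-0.6285761157543256	-0.31281659247298577	-0.6781598498549376	-2.160497187761005	0.8691370906734631	-0.2979272795639148	-2.1092925224196604	-0.5543565800567748	0.8181205258993774	0.91697506555553	0.7877402768662645	-0.649342113671172
G007	-0.4232419724206728	0.6808923750510223	-1.0321593122873642	-0.03976577640856258	-1.5159876202756304	1.140421186625302	-0.2673744835789293	-0.45712357786340374	-1.2098749407473066	-0.007584149001112318	-0.7819418794916001	-0.5212661317081029	1.2581652190285826	-0.17150329303574516	-1.0472200368297977	0.15946662307181642	-0.35442543429607326	0.5764920366208567	1.399594699536853	-0.9699426893161182	0.4442309450290117	0.08295242527849278	0.8750416464306509	-0.22451224678475676
G008	1.6409432394541026	-2.0164705308067084	2.1848750248835564	2.395397661040954	-0.27991338609413585	-0.3020085783231211	0.8133585505525519	1.7138330872913778	1.8563416321966555	-0.9290654136693055	-1.0126842711900501	0.3871183209419308	0.9148066246625123	-0.607279701443752	-3.9630162532423823	-1.0482014002613165	1.8217261874933262	-1.3744692893791597	-3.5966308234477506	0.13535232628798957	0.5266746617748941	1.8852643937836109	-2.090817985208058	-1.499392613496959
G009	2.358926456659427	-0.6928879143061686	1.9367712996854063	3.8700928928183065	-0.06624541793107051	-1.6728170416152885	0.8358145284924594	2.703870616624462	4.036961840992668	-2.4625165408694083	-1.929225307790768	-0.5485933747973223	4.366517166257213	3.5710100508582867	1.2451099248189217	2.0392496186757505	8.40791790573608	3.8866864976874202	1.8513141661895438	5.271477658893309	5.4610296611296105	6.333287381059133	4.8528547073371495	3.481512391275115
G010	0.714511636039423	-0.37594787871553276	1.156509979329735	2.9366613781972415	-1.2418401483203572	1.0716871807131674	0.416024549596732	3.1006421142546263	3.6158040686247745	-2.90691277944138	-0.09623680834677831	-0.42015288116292415	1.5849433303840226	-2.041943940328225	-5.146952090562338	-3.3877444244523236	2.643365619573796	0.26186998655319305	-3.7321857499595934	0.38201421023716314	0.4111865000012736	1.94583222107308	-0.07166893231750833	0.005701744055003548
G011	1.22024311794179	-1.3489965903836296	2.002981150684542	0.9935688606393347	-0.02610517227434843	0.6874829955436733	-0.9491237125103992	-1.071035311488288	0.047926347546842336	-1.1710295798893746	0.18566427813402597	1.267965997645276	-1.010180139411861	-0.7215176935721246	0.04549682016402531	-0.9942755748188715	-0.37450013036597063	0.8527542231235605	0.9473256700729591	0.37504993983009693	-1.8091230256657584	-0.05275927796909618	1.0403714981920815	0.7945588112113147
G012	0.2547984422683697	-2.3561924009161586	-0.014422259579861669	1.614460151156251	-0.021243908208147307	1.561082334807305	0.3779497923268256	0.5223140810538333	2.8742427788304075	-0.5087226137495877	-1.4085676187387546	1.2569597255787262	5.221251570604439	4.2080035326567105	0.12435118269279055	1.3432088679630776	5.142354469546307	3.4299274796908503	2.6990808924790146	5.884363593069027	3.6482661319337044	2.8575886557303045	3.5682937513136723	2.749789479681277
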
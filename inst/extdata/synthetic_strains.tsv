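strain	t1	t2	t3	t4	t5	t6
s1	-0.193559258940797	0.0485391856223256	0.0852222853941256	0.190633114098587	0.104447436270437	0.270138717171159
s2	0.171688794980398	-0.0444253476696187	0.235976803291939	-0.179264874599447	0.0839129528649414	0.144286862919266
s3	0.0951302392239752	-0.0565635036145213	0.108686377202253	-0.0119415921187236	0.0985969479756758	0.101240924436378
s4	-0.0921020564034615	-0.168344324651826	-0.150899658419365	0.0270746876238254	-0.100302805614404	-0.0968663323957201
s5	-0.0258738422636406	0.0125263850625427	0.0293075649097945	0.0689973413302753	0.0320091259179612	0.0978409213495882
s6	0.0461737418877513	0.0731016692779631	0.0213110198475445	0.00539158292039423	-0.0684912006398411	0.0913849755493755
s7	0.0944088520057138	-0.0566702189049074	0.188166435604793	-0.110206636536065	-0.0990747056560438	-0.11271182858958
s8	0.152224800579293	-0.0515916430520353	0.136756841815033	-0.0663439538353101	0.141250369061179	-0.00264389724038784
s9	-0.0862490789477179	-0.161931829508223	-0.162739028769689	0.0370717873263529	-0.083001857711385	-0.0120116350147459
s10	-0.0578220924743666	-0.158561971541822	-0.162886593020065	0.0174247850985414	-0.0399976003682331	0.0214222668142183
s11	0.127596438449948	-0.0375521856034097	0.149998971591885	-0.0604080344930299	0.0942531664912306	-0.0235181900831427
s12	0.156793298130306	-0.0315069121906509	0.246759225935597	-0.164711123056682	0.0826369217537615	0.136271594642751
s13	-0.155684620749779	-0.121554411867405	-0.0937914063395804	0.0375874600458561	-0.00530360148389379	-0.0331760449691777
s14	-0.25196191086773	0.194726608180509	0.118590559035712	0.129716644276906	0.111202543214349	0.260838904192001
s15	0.0809074255463968	0.0490413196999799	0.0548375252823703	-0.0541323100736471	-0.00725919714017798	0.0938652484340857
s16	-0.0616707301562898	0.0311189955440682	0.13953531342192	0.133111121992167	0.00464331775405304	-0.0316241389514903
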
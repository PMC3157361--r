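# pssm allele_id=HLA_EXAMPLE mhc_class=I binder_threshold=4.337615598
pos	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
1	0.653918256393748	-0.83520828826214	3.03220942340345	1.18802813734496	0.109411844704592	-0.547233104761525	1.54294423416711	0.803079096215562	-1.1156270316817	0.294065006967276	1.16943259250818	-0.380266400186711	-0.365349144564453	1.49190981636726	-0.917422744321486	-1.02660891989908	-1.04072171686758	-0.724933413307226	-1.01557597223513	0.785272852880047
2	0.0190522715695512	0.361940981705761	1.19840893637023	1.51562024473401	0.109466819508546	-0.211857135738966	1.14085772942722	1.48096717683083	0.0515412404503362	-3.22457312047903	1.53911445320904	-0.0783565103972955	0.988953204832321	-0.414248324725457	1.0778740570054	-0.623336917217416	0.0584665328773453	-0.615165178808662	-0.387369823139576	-2.44126157152182
3	-1.84950398071878	-0.323785443190916	0.055879403189074	0.183363638550743	-0.159062291338414	-0.475788481807454	0.589836487755498	-0.694626445229017	0.734139708006527	-1.0376709199725	-0.764023787199276	2.65317896071627	-0.236088663886246	1.30272093190927	-0.695491315246152	-1.3106226013491	1.76305500160652	-0.243391969123683	0.467726934447894	0.231728952024174
4	-0.132763311902842	-0.729867884540752	0.414424888456787	-0.0685546962309646	-0.19977064190036	1.93870809426185	-2.25048062369263	-0.319342243490249	-0.65350812643639	0.68863215067765	0.157348053572707	-1.52273944655334	-0.523263398190512	-0.280418990023713	1.29376534595111	1.0134763800327	0.923601757084231	0.67714120243193	-0.496277772502512	0.509151525955324
5	-1.19881818453734	-0.704604609379489	-0.929409186497067	1.65073486888539	-0.174922746511664	-0.962716372899704	-0.557274071027089	0.188872305109366	-0.466106078168786	0.635521637376752	-0.801834657796283	0.244325344140868	-1.59290989632536	0.464218560590097	0.346159827761854	-0.169185365308206	-0.824991849300456	-1.64781155818156	0.511466640765695	-0.422972017856949
6	-1.32974147213541	-0.362183319729528	-0.657349264553431	1.42595651313264	-0.33907756402543	-2.63437173753016	-1.75725881637353	-0.499980027618825	-0.508993054502753	-0.772652213842249	-0.155415295606991	-0.944253237887955	-0.607659502341073	0.634149100894331	-1.14478612259553	1.89865320811098	1.19955189347928	1.08264317371708	-0.393105322246571	-0.146294845087598
7	0.916493229014068	0.134096834277367	-0.0340638691420121	-1.43388303174232	-0.126307397117531	0.29311216361783	1.0142314529461	1.11456101228284	-1.70913597812364	-0.619910134426749	-1.59409445922281	1.42230070022563	0.361941018707119	0.847796513310937	1.72082890805105	0.568242485675737	-0.350311016377877	0.507330289965569	-0.474211779841828	-0.643047920407768
8	-0.162954996260064	1.63936150352692	-2.25820390745654	0.125756418420499	0.980467210073315	-2.23140147893235	-0.684698306374162	0.42536913390213	1.0597779467201	0.445044946721493	-0.24327582537508	-0.325441889322827	-0.667041218293031	-0.00298964733921755	-1.73909771024368	-0.76542323366092	0.0356027863581074	-0.419869437026359	-0.258039810375838	1.58240769497314
9	-1.60211864501153	-1.39958738896335	-0.523747923418715	0.673440094399147	2.4742333200607	-1.42817665788538	-2.5063516781401	-1.34453855749348	0.239167736854694	0.294012109128733	0.538963690739203	-0.236010691495564	-0.540334982461746	1.44200678951362	0.00850480131589891	-0.162923103069071	0.47144415383358	-0.614740943947007	-0.395786716718196	-1.72916670291237
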
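"species","female_weight","female_group_size","male_group_size","female_sexual_maturity","life_span","innovation","fruit","total_brain","neocortex"
"t1",-0.748622154180396,1.91996962353579,0.97493010325319,1.28865684132704,2.4648029171285,0.551621587987807,0.43743491483276,5.58725848635202,5.01403199887651
"t2",3.13325999743816,3.14445043402239,1.67935489368152,1.73625803238895,3.52324301955393,1.99037045721073,1.05156215688449,8.25164966574828,7.42418258169543
"t3",2.30702162543759,2.4715960991945,1.57856671028204,1.64198178809261,3.15389134188802,1.970637696438,0.673370134693243,7.42185536829355,6.86436076263992
"t4",3.04520740860597,3.19368259292151,1.65828465885165,1.85152023217332,3.5668744395463,1.58983593026763,1.37546301005408,8.15511127645747,7.53061113566564
"t5",3.09953957066158,2.34081153628121,2.07690578068395,1.81954721208136,3.40021938946918,1.05320010649942,1.01936721852981,7.97436407911866,7.28416981468334
"t6",1.17386351771854,2.63433027175984,2.00423683767317,1.31327209967353,2.84243258500477,1.92916172698654,0.725861549564143,6.80170317745242,6.06822603232942
"t7",3.30520003741487,2.99852415970664,1.54882674085569,1.96914813746144,3.62395270366713,1.61335793659494,1.25182234703005,8.47824657236695,7.70487156569966
"t8",3.21003412050414,2.41071183237221,1.73692818299799,1.64726676506478,3.59209124056357,0.738055523236312,0.626058132232747,7.9768020866992,7.40574662007077
"t9",1.25044173964817,2.59311240579881,1.88318374110013,1.62654915851633,2.78827987762177,1.67256772179222,0.683430404419994,6.71383304826173,6.05318787416774
"t10",3.6308335789753,2.40359676093324,1.23455520194672,2.3514391158312,3.64057514439084,1.23928241578404,0.822476241091546,8.39174199131894,7.87178863556862
"t11",2.58254311580308,2.80996020239117,1.78721649656783,1.86452705675408,3.19973642657111,1.41532165050546,0.519855367028152,7.70025110415716,7.21237006388007
"t12",3.93782369610597,2.72212983472316,2.18685621366414,1.96115295092132,3.55105104434268,1.16865895805163,1.08696052440106,8.55003269301187,7.97542414304272
"t13",2.69302968566185,2.32955145386183,0.791016333293011,1.57087444145475,3.26682259783102,1.08558244910261,0.724107802484195,7.8610134038197,6.87709926751621
"t14",3.4486104397369,3.24365846679335,1.81758590610784,1.7493756592898,3.55224747264221,1.82365520918308,1.09135076531891,8.34572158958678,7.77676319336221
"t15",3.18889805238586,2.34530012220683,2.32710716595113,1.78501846940058,3.25156643918484,1.29131664022372,0.659083888802343,7.72973183074422,7.12485280623117
"t16",4.41892033655103,3.11346265882099,1.59058945553049,1.93604847448629,3.21365668956428,1.17709247697353,0.82296476347943,8.83406042769689,8.11620451646633
"t17",3.84653452346261,2.86256557168829,1.25904481853338,2.2392515205275,3.56793552638985,1.52788789238398,0.939946223824818,8.66327807370446,7.80174944268654
"t18",2.84439566745868,2.47570752615858,1.03892008796672,1.65241805469693,3.34293008747122,0.84468976128933,0.817795314658808,7.97422269404484,7.02470320029169
"t19",2.02538682299659,2.77437224346395,1.81581644956281,1.61963440412315,3.2358120475075,1.88786889553496,0.743085635418158,7.38476534164777,6.65900839685485
"t20",3.19882201164523,2.51633066427554,1.24918143630954,1.68556966470369,3.08608677563483,1.50593256383574,0.735088162010715,7.92238949450294,7.25788001982041
"t21",3.23526294879337,2.47433037787539,0.836771546316005,1.45495404553197,3.22761136152803,1.21493360627272,0.819860287439009,8.12858618072864,7.17629228562416
"t22",3.47080661062802,3.49977979299028,2.02172973128583,1.86587032799429,3.62645417135894,1.77283839819115,1.27619452536759,8.37321376645543,7.81136746163366
"t23",2.67316468023976,3.58449663679031,2.03649281424315,1.61931333579349,3.38221160198812,1.28729687226868,1.00603572865317,7.8020159577406,7.32386834377174
"t24",4.35115024053615,3.16265162555557,1.65458208506534,2.04858515775874,3.30615856991287,0.997688016174242,0.92426671153945,8.83745685149758,8.16508391641722
"t25",4.74566107600398,2.88980506598129,1.42194400143832,1.96628408816879,3.84480885804539,1.6276418707438,0.717815761903975,9.18156655444331,8.35461274694311
"t26",3.43771220294894,3.06637727865617,2.19854319339075,2.0664689185764,3.19359408313383,1.4935055532753,0.755915118919697,8.30609446460235,7.68408567090594
"t27",5.16186106376931,3.18854400492473,1.6230864285927,2.69381204259591,3.79939280959567,1.9522531983437,1.01189783890642,9.63967730605873,8.79280014520583
"t28",3.64272728729953,2.48290528321452,1.07016973713324,1.71014705550941,3.37385406130383,0.972615901457471,0.839659710708781,8.3036484689361,7.73547669413318
"t29",2.41709736013287,2.53095990697469,1.9571808066701,1.64487606614866,3.03477293239365,1.80305617501806,0.817492443146722,7.63303576313253,6.9522856267072
"t30",0.68697935830291,2.46062269716515,1.41438970129687,1.58448815615502,3.11348575456243,1.18194799929686,0.471204513900091,6.41003688753853,5.98332443386949
"t31",1.72930926247964,2.81272054747849,1.90352572909942,1.49221653888393,2.851827680388,2.19796593160505,0.704595107484231,7.14941172517889,6.41841847207888
"t32",-0.402710106327083,1.96241579560217,1.07976169078153,1.27451793638636,2.38395341457424,1.05109458538396,0.252655434263596,5.68175390667617,5.14971254962203
"t33",3.76937532874446,2.93306308183984,1.29350426006923,2.01938152675282,3.35357907002004,1.05088545072843,0.327696707767761,8.1991000252146,7.81593588619009
"t34",3.2694694339915,2.4502834025607,0.921964103602565,1.46525672134833,3.3030068370817,0.795613652080754,0.791580189769002,8.19928101029509,7.27540888771173
"t35",1.99191094412085,2.84978158551251,2.00959233788113,1.7445605028623,3.32750443515762,2.08143981038856,0.86857607491437,7.47693977038002,6.67985418782293
"t36",2.17036850639365,2.87241222285172,1.78386750337464,1.77615092711086,3.47149120388845,1.51881436053394,1.26729110371907,7.61736443118584,6.88412083617701
"t37",1.07301081699607,2.58349743110216,1.11221289999333,1.22868299400486,3.05069052896331,-0.0363426501426634,0.792480793858971,6.7742815420312,5.71317934943921
"t38",2.09186740094625,2.59580565607061,1.76283470663549,1.60825197648025,2.95831007697549,0.778548688581365,0.175603499778683,7.31094709149799,6.79843021432546
"t39",2.7748691491993,1.95114707006752,1.52460340724983,2.09163378257435,3.39729861100911,1.14404039875197,0.236431890215107,7.58711545889509,7.00837907024927
"t40",4.20636903175836,2.82182386382439,1.49325977942146,1.82345765640953,3.36587627063098,0.932504715163226,0.768590038563617,8.56393580217746,7.94131254180989
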
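"t","hx","hy","hz"
0,0,0,0
6.4e-06,0,0,0
1.28e-05,0.587150637081632,0.587150637081632,0
1.92e-05,0.242404766456266,0.242404766456266,0.45293398018842
2.56e-05,0.100076653399845,0.100076653399845,0.247784789779096
3.2e-05,0.0413165825991285,0.0413165825991285,0.135554638714299
3.84e-05,0.0170575248040143,0.0170575248040143,0.0741573366684282
4.48e-05,0.00704218824830159,0.00704218824830159,0.0405689590110243
5.12e-05,0.00290736293186253,0.00290736293186253,0.0221938989340602
5.76e-05,0.00120030293419193,0.00120030293419193,0.0121415279539568
6.4e-05,0.000495544301690185,0.000495544301690185,0.00664221737220216
7.04e-05,0.00020458514925062,0.00020458514925062,0.00363373142053396
7.68e-05,8.4462848530678e-05,8.4462848530678e-05,0.00198789098529579
8.32e-05,3.48704332061611e-05,3.48704332061611e-05,0.00108750760914509
8.96e-05,1.43962361338512e-05,1.43962361338512e-05,0.000594938459249811
9.6e-05,5.94347691628284e-06,5.94347691628284e-06,0.000325470614934627
0.0001024,2.4537606584074e-06,2.4537606584074e-06,0.000178053913877914
0.0001088,1.01303352457765e-06,1.01303352457765e-06,9.74072459770643e-05
0.0001152,4.18230245236834e-07,4.18230245236834e-07,5.328819435748e-05
0.0001216,1.72666090299219e-07,1.72666090299219e-07,2.91521603900924e-05
0.000128,7.12850853776383e-08,7.12850853776383e-08,1.59481563535167e-05
0.0001344,2.94300020837395e-08,2.94300020837395e-08,8.72469441965111e-06
0.0001408,1.21501576109581e-08,1.21501576109581e-08,4.77298385023083e-06
0.0001472,5.0161848290418e-09,5.0161848290418e-09,2.61113727757073e-06
0.0001536,2.0709287109507e-09,2.0709287109507e-09,1.42846447762226e-06
0.00016,8.54981598965355e-10,8.54981598965355e-10,7.8146437621504e-07
0.0001664,3.52978608439775e-10,3.52978608439775e-10,4.27512605920501e-07
0.0001728,1.45726993618173e-10,1.45726993618173e-10,2.33877619740204e-07
0.0001792,6.01632964752718e-11,6.01632964752718e-11,1.2794649855428e-07
0.0001856,2.4838378620885e-11,2.4838378620885e-11,6.99951817129179e-08
0.000192,1.02545087895576e-11,1.02545087895576e-11,3.82919854656742e-08
0.0001984,4.23356742080965e-12,4.23356742080965e-12,2.09482440793893e-08
0.0002048,1.74782561255322e-12,1.74782561255322e-12,1.1460072510553e-08
0.0002112,7.21588690635008e-13,7.21588690635008e-13,6.26941625510031e-09
0.0002176,2.97907431217763e-13,2.97907431217763e-13,3.42978459721975e-09
0.000224,1.22990893186901e-13,1.22990893186901e-13,1.87631860841207e-09
0.0002304,5.07767118969731e-14,5.07767118969731e-14,1.02647015300239e-09
0.0002368,2.09631331577549e-14,2.09631331577549e-14,5.61546941058402e-10
0.0002432,8.65461616895203e-15,8.65461616895203e-15,3.07203249982187e-10
0.0002496,3.57305277165486e-15,3.57305277165486e-15,1.68060459240937e-10
0.000256,1.47513256045141e-15,1.47513256045141e-15,9.19401665246455e-11
0.0002624,6.09007537802515e-16,6.09007537802515e-16,5.02973409614517e-11
0.0002688,2.51428373994252e-16,2.51428373994252e-16,2.75159661268873e-11
0.0002752,1.03802044023128e-16,1.03802044023128e-16,1.50530500703065e-11
0.0002816,4.28546077445726e-17,4.28546077445726e-17,8.23501218798695e-12
0.000288,1.76924975054634e-17,1.76924975054634e-17,4.50509534078188e-12
0.0002944,7.30433632356543e-18,7.30433632356543e-18,2.46458457695323e-12
0.0003008,3.01559059772547e-18,3.01559059772547e-18,1.34829047500281e-12
0.0003072,1.24498465709359e-18,1.24498465709359e-18,7.37603903709654e-13
0.0003136,5.1399112252423e-19,5.1399112252423e-19,4.03518031799923e-13
0.00032,2.12200907479826e-19,2.12200907479826e-19,2.20751003578987e-13
0.0003264,8.76070094637462e-20,8.76070094637462e-20,1.20765372897368e-13
0.0003328,3.6168498044291e-20,3.6168498044291e-20,6.60666318820244e-14
0.0003392,1.49321413752997e-20,1.49321413752997e-20,3.61428093460557e-14
0.0003456,6.16472505379949e-21,6.16472505379949e-21,1.97725028537555e-14
0.000352,2.54510281102803e-21,2.54510281102803e-21,1.08168644379171e-14
0.0003584,1.05074407409468e-21,1.05074407409468e-21,5.91753897489273e-15
0.0003648,4.33799021580237e-22,4.33799021580237e-22,3.23728449407447e-15
0.0003712,1.79093649694013e-22,1.79093649694013e-22,1.77100834317107e-15
0.0003776,7.39386991788985e-23,7.39386991788985e-23,9.68858485351697e-16
0.000384,3.0525544851021e-23,3.0525544851021e-23,5.30029555342026e-16
0.0003904,1.26024517444802e-23,1.26024517444802e-23,2.89961159223464e-16
0.0003968,5.2029141739181e-24,5.2029141739181e-24,1.58627897276331e-16
0.0004032,2.14801980202105e-24,2.14801980202105e-24,8.67799323940428e-17
0.0004096,8.86808606800425e-25,8.86808606800425e-25,4.7474352214327e-17
0.000416,3.66118368348083e-25,3.66118368348083e-25,2.5971604909025e-17
0.0004224,1.51151735125219e-25,1.51151735125219e-25,1.42081825256992e-17
0.0004288,6.24028975504525e-26,6.24028975504525e-26,7.77281386309072e-18
0.0004352,2.57629964979646e-26,2.57629964979646e-26,4.25224234281728e-18
0.0004416,1.06362366910527e-26,1.06362366910527e-26,2.32625729375931e-18
0.000448,4.39116354175012e-27,4.39116354175012e-27,1.27261631875456e-18
0.0004544,1.81288907068191e-27,1.81288907068191e-27,6.96205144248324e-19
0.0004608,7.48450097872697e-28,7.48450097872697e-28,3.80870177236278e-19
0.0004672,3.08997146082935e-28,3.08997146082935e-28,2.08361131925582e-19
0.0004736,1.27569274903934e-28,1.27569274903934e-28,1.13987295125964e-19
0.00048,5.26668938720473e-29,5.26668938720473e-29,6.23585758536485e-20
0.0004864,2.17434935819638e-29,2.17434935819638e-29,3.41142578933738e-20
0.0004928,8.97678747293355e-30,8.97678747293355e-30,1.86627512845539e-20
0.0004992,3.70606098925417e-30,3.70606098925417e-30,1.02097570639743e-20
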
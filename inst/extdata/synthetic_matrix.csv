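,0,4.743416490252567e-10,1.4999999999999998e-09,4.7434164902525685e-09,1.5e-08,4.743416490252569e-08,1.5000000000000002e-07,4.7434164902525693e-07
0,1001.9281877037358;1005.8475135482597;948.5498026571826,1002.3430136357111;997.9127351713005;986.552474581127,915.1540998862681;935.3949907542515;926.6951829731689,777.0274801314299;797.869762577033;794.3529552500487,518.0810031940256;476.70804491194764;498.7691144814892,184.53698618411144;212.79201168130078;227.93597317810702,44.239968787988516;60.845713644712916;41.39970726360467,-17.787890817207305;22.420204522398404;-1.8504972446930452
2.2135943621178653e-09,1022.3530764630584;1028.1229238039812;984.43592442082,923.637805079168;926.2098887269328;893.7854989591443,858.3850378861782;876.1033596021869;876.0135691895141,748.8988173620975;779.9561937767951;732.566245475411,500.264582265563;471.1620739838401;506.73080207331475,208.13176325534224;195.89463542713304;181.6416308765433,52.655863897222744;62.89815088225617;53.14701206968067,20.84155039787193;18.102442152881878;-15.391196071427515
7e-09,923.1858008332541;906.3047785994049;944.6603907033924,795.5684649838952;798.8226592685909;763.3943496381208,737.8981786473748;760.5240737765305;758.547998038824,616.818346137694;682.0997913765101;644.5940742171562,432.748803066351;444.9059085157965;447.88269983853814,229.79054750262566;193.29792039827163;192.08509356747223,71.73225113709096;45.926823864603705;67.2339165434418,0.8533888352196985;0.8348511210525285;-16.412609664645025
2.2135943621178658e-08,797.0571559666244;767.2943519426696;822.625918058089,521.0215827423425;482.33476555668676;511.28005715162067,478.6830414856747;496.5763808711998;470.10329609641826,444.4618008723984;402.07238540487674;466.34890624315335,277.59230828881715;301.2481728874585;305.8754114912042,146.00177040263776;194.1080983042953;175.37507803946235,68.49484006543015;100.73113655815902;52.25020076152434,21.412751460570604;19.941362952064875;21.42308346604124
7e-08,471.9821343110898;475.90766180216684;484.840819609705,252.62751618489776;190.54979411445808;234.51895757522783,182.26930679084245;242.35905356956724;244.75188814311895,193.62556162036148;164.24528390236742;192.22824456390669,184.89301499863143;188.48785160280815;172.60617726299935,105.78125412980921;70.55110952711605;99.11055932407238,23.208888713939665;60.4740271551225;25.298929307963775,-6.46324604654958;18.296211107776216;5.489832016568416
2.2135943621178657e-07,197.01876283973877;196.48781983600904;176.12945831005732,50.591990235587076;50.931181296140515;54.79674293981832,58.071745579254625;41.04196331490962;76.91451868284062,75.76900945858497;83.62397190694378;85.75186433006436,33.854051301995305;15.750612553746812;66.47543360145664,63.865152824386676;10.913344188877986;47.36705960376055,38.2811317197004;35.74865127342498;32.94220668928094,-20.783701829259137;27.344087397951327;19.415318349318976
7.000000000000002e-07,32.36395206024926;84.80652191899827;66.82259891878766,68.40937519521614;28.59234115472221;19.629904480533792,14.280872093208934;17.391652997722623;59.41745471336599,3.156460480882492;23.23154134099027;56.48288464362131,49.214583404007584;26.036934476704445;7.688207793708077,39.9505740975124;19.334200221607183;4.944945420813241,1.3513628574152996;44.468106194463275;51.82776337898703,19.412064220450276;2.107497589085077;-7.6606520098484125
2.2135943621178663e-06,3.770901525878134;43.9083267486062;10.957600223320885,12.630516336363572;-0.2665157672091203;51.32839511007843,7.1356968128290985;26.527628373681623;-17.452281201016056,-6.701763824883529;25.381053396466744;8.295146265181689,-27.073175348008423;-2.932607802682903;4.044299937081308,2.291450545133981;17.186016327795254;15.707344206849811,-25.076676206370927;0.8271488464288881;18.19965946633961,-17.703308419849634;13.09516967163578;8.642161761178926
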
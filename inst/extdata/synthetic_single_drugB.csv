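drug,dose,replicate,response
drugB,0,1,981.3024408133755
drugB,0,2,986.122741264446
drugB,0,3,989.0410988538578
drugB,2.2135943621178653e-09,1,999.7237567029499
drugB,2.2135943621178653e-09,2,1021.4403410394655
drugB,2.2135943621178653e-09,3,999.4808059158876
drugB,7e-09,1,918.9494734929747
drugB,7e-09,2,928.0581204253608
drugB,7e-09,3,908.9699077031505
drugB,2.2135943621178658e-08,1,784.2442365726741
drugB,2.2135943621178658e-08,2,771.0851971149592
drugB,2.2135943621178658e-08,3,788.7829431980012
drugB,7e-08,1,511.47508575474745
drugB,7e-08,2,524.7700955125727
drugB,7e-08,3,496.52236540710624
drugB,2.2135943621178657e-07,1,175.2076912418765
drugB,2.2135943621178657e-07,2,221.43814306485717
drugB,2.2135943621178657e-07,3,202.4135890618798
drugB,7.000000000000002e-07,1,60.74710510750133
drugB,7.000000000000002e-07,2,103.66968447112694
drugB,7.000000000000002e-07,3,83.1838927499555
drugB,2.2135943621178663e-06,1,20.179610735352977
drugB,2.2135943621178663e-06,2,20.81452252579343
drugB,2.2135943621178663e-06,3,-8.784826731167094
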
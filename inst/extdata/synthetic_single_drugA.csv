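drug,dose,replicate,response
drugA,0,1,1010.4117814583705
drugA,0,2,978.4061847529543
drugA,0,3,1002.7847623003855
drugA,4.743416490252567e-10,1,982.7033620591989
drugA,4.743416490252567e-10,2,971.0655454524785
drugA,4.743416490252567e-10,3,934.0765571179813
drugA,1.4999999999999998e-09,1,925.9461209480988
drugA,1.4999999999999998e-09,2,920.2466116345306
drugA,1.4999999999999998e-09,3,942.9201457231785
drugA,4.7434164902525685e-09,1,789.7641714500963
drugA,4.7434164902525685e-09,2,791.0756970001397
drugA,4.7434164902525685e-09,3,784.631325515026
drugA,1.5e-08,1,495.57126801187655
drugA,1.5e-08,2,495.483669511421
drugA,1.5e-08,3,449.0623710774341
drugA,4.743416490252569e-08,1,227.7000388990424
drugA,4.743416490252569e-08,2,213.08817183010115
drugA,4.743416490252569e-08,3,205.1112956792595
drugA,1.5000000000000002e-07,1,43.25656649476241
drugA,1.5000000000000002e-07,2,73.14587865528406
drugA,1.5000000000000002e-07,3,52.77750282096288
drugA,4.7434164902525693e-07,1,12.308030703312767
drugA,4.7434164902525693e-07,2,-12.23891535359651
drugA,4.7434164902525693e-07,3,44.918157465857405
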
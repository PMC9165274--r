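wavelength_nm,HbO,HbR,PBB5
550,0.858534,0.99301,0.0625
555,0.75472,0.996505,0.0874362
560,0.650906,1,0.1197
565,0.769489,0.918978,0.160359
570,0.888073,0.837956,0.210224
575,0.944036,0.763107,0.26969
580,1,0.688258,0.338564
585,0.639709,0.591396,0.415919
590,0.279419,0.494534,0.5
595,0.171643,0.383701,0.588198
600,0.0638672,0.272868,0.677128
605,0.0469623,0.24129,0.762799
610,0.0300575,0.209712,0.840896
615,0.0244292,0.186845,0.907126
620,0.0188009,0.163977,0.957603
625,0.0154878,0.142504,0.989228
630,0.0121747,0.121031,1
635,0.0104982,0.108379,0.995198
640,0.00882165,0.0957277,0.98093
645,0.00808319,0.0882539,0.957603
650,0.00734472,0.0807801,0.925875
655,0.00685574,0.0752491,0.886621
660,0.00636676,0.0697182,0.840896
665,0.00611728,0.0648565,0.789889
670,0.00586779,0.0599948,0.734867
675,0.00569815,0.0564531,0.677128
680,0.0055285,0.0529114,0.617947
685,0.00551852,0.0492954,0.558536
690,0.00550854,0.0456793,0.5
695,0.00564825,0.043625,0.44331
700,0.00578796,0.0415706,0.389282
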
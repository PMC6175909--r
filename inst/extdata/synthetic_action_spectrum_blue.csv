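"wavelength_nm","response"
400,0.0336
405,0.05362
410,0.08266
415,0.12309
420,0.17705
425,0.24602
430,0.33021
435,0.42813
440,0.53619
445,0.64867
450,0.75805
455,0.85572
460,0.93309
465,0.98284
470,1
475,0.98284
480,0.93309
485,0.85572
490,0.75805
495,0.64867
500,0.53619
505,0.42813
510,0.33021
515,0.24602
520,0.17705
525,0.12309
530,0.08266
535,0.05362
540,0.0336
545,0.02033
550,0.01189
555,0.00671
560,0.00366
565,0.00193
570,0.00098
575,0.00048
580,0.00023
585,0.00011
590,5e-05
595,2e-05
600,1e-05
605,0
610,0
615,0
620,0
625,0
630,0
635,0
640,0
645,0
650,0
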
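"wavelength_nm","response"
400,0.00146
405,0.00254
410,0.00432
415,0.00717
420,0.0116
425,0.01832
430,0.02822
435,0.0424
440,0.06218
445,0.08894
450,0.12413
455,0.16901
460,0.22451
465,0.29096
470,0.36788
475,0.45379
480,0.54611
485,0.64118
490,0.73444
495,0.82075
500,0.89484
505,0.95182
510,0.98773
515,1
520,0.98773
525,0.95182
530,0.89484
535,0.82075
540,0.73444
545,0.64118
550,0.54611
555,0.45379
560,0.36788
565,0.29096
570,0.22451
575,0.16901
580,0.12413
585,0.08894
590,0.06218
595,0.0424
600,0.02822
605,0.01832
610,0.0116
615,0.00717
620,0.00432
625,0.00254
630,0.00146
635,0.00082
640,0.00045
645,0.00024
650,0.00012
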
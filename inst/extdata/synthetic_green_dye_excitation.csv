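"wavelength_nm","value"
412,1e-04
413,0.000126
414,0.000156
415,0.000195
416,0.000241
417,0.000298
418,0.000368
419,0.000452
420,0.000554
421,0.000678
422,0.000827
423,0.001006
424,0.00122
425,0.001476
426,0.00178
427,0.002142
428,0.002569
429,0.003074
430,0.003668
431,0.004364
432,0.005179
433,0.006129
434,0.007233
435,0.008513
436,0.009993
437,0.011697
438,0.013654
439,0.015895
440,0.018453
441,0.021364
442,0.024668
443,0.028404
444,0.032616
445,0.037351
446,0.042656
447,0.048581
448,0.055178
449,0.0625
450,0.0706
451,0.079531
452,0.089347
453,0.100099
454,0.11184
455,0.124616
456,0.138471
457,0.153446
458,0.169576
459,0.186888
460,0.205405
461,0.225139
462,0.246094
463,0.268265
464,0.291632
465,0.316168
466,0.341832
467,0.368567
468,0.396307
469,0.42497
470,0.454459
471,0.484666
472,0.515467
473,0.546726
474,0.578295
475,0.610014
476,0.641713
477,0.673213
478,0.704329
479,0.734867
480,0.764633
481,0.793429
482,0.821058
483,0.847325
484,0.872042
485,0.895025
486,0.916102
487,0.935111
488,0.951905
489,0.96635
490,0.978331
491,0.987753
492,0.994538
493,0.998632
494,1
495,0.998632
496,0.994538
497,0.987753
498,0.978331
499,0.96635
500,0.951905
501,0.935111
502,0.916102
503,0.895025
504,0.872042
505,0.847325
506,0.821058
507,0.793429
508,0.764633
509,0.734867
510,0.704329
511,0.673213
512,0.641713
513,0.610014
514,0.578295
515,0.546726
516,0.515467
517,0.484666
518,0.454459
519,0.42497
520,0.396307
521,0.368567
522,0.341832
523,0.316168
524,0.291632
525,0.268265
526,0.246094
527,0.225139
528,0.205405
529,0.186888
530,0.169576
531,0.153446
532,0.138471
533,0.124616
534,0.11184
535,0.100099
536,0.089347
537,0.079531
538,0.0706
539,0.0625
540,0.055178
541,0.048581
542,0.042656
543,0.037351
544,0.032616
545,0.028404
546,0.024668
547,0.021364
548,0.018453
549,0.015895
550,0.013654
551,0.011697
552,0.009993
553,0.008513
554,0.007233
555,0.006129
556,0.005179
557,0.004364
558,0.003668
559,0.003074
560,0.002569
561,0.002142
562,0.00178
563,0.001476
564,0.00122
565,0.001006
566,0.000827
567,0.000678
568,0.000554
569,0.000452
570,0.000368
571,0.000298
572,0.000241
573,0.000195
574,0.000156
575,0.000126
576,1e-04
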
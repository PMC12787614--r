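wavelength,irradiance
300,16.3402
301,16.4452
302,16.5523
303,16.6613
304,16.7724
305,16.8855
306,17.0007
307,17.118
308,17.2375
309,17.3591
310,17.483
311,17.6091
312,17.7374
313,17.8681
314,18.0011
315,18.1364
316,18.2741
317,18.4142
318,18.5567
319,18.7017
320,18.8492
321,18.9992
322,19.1517
323,19.3069
324,19.4646
325,19.6249
326,19.7879
327,19.9536
328,20.1219
329,20.293
330,20.4668
331,20.6434
332,20.8228
333,21.005
334,21.19
335,21.3779
336,21.5687
337,21.7623
338,21.9589
339,22.1583
340,22.3607
341,22.5661
342,22.7744
343,22.9857
344,23.2
345,23.4173
346,23.6375
347,23.8609
348,24.0872
349,24.3165
350,24.5489
351,24.7843
352,25.0228
353,25.2642
354,25.5087
355,25.7562
356,26.0068
357,26.2603
358,26.5169
359,26.7764
360,27.0389
361,27.3044
362,27.5729
363,27.8442
364,28.1185
365,28.3957
366,28.6757
367,28.9586
368,29.2443
369,29.5328
370,29.8241
371,30.118
372,30.4147
373,30.714
374,31.016
375,31.3205
376,31.6276
377,31.9371
378,32.2491
379,32.5636
380,32.8803
381,33.1994
382,33.5207
383,33.8443
384,34.17
385,34.4978
386,34.8276
387,35.1594
388,35.4931
389,35.8287
390,36.166
391,36.5051
392,36.8459
393,37.1883
394,37.5322
395,37.8776
396,38.2244
397,38.5726
398,38.9221
399,39.2727
400,39.6245
401,39.9774
402,40.3313
403,40.6862
404,41.042
405,41.3986
406,41.7559
407,42.114
408,42.4727
409,42.832
410,43.1919
411,43.5522
412,43.913
413,44.2742
414,44.6357
415,44.9975
416,45.3595
417,45.7218
418,46.0843
419,46.4469
420,46.8097
421,47.1725
422,47.5355
423,47.8986
424,48.2617
425,48.6249
426,48.9882
427,49.3515
428,49.715
429,50.0785
430,50.4422
431,50.806
432,51.1701
433,51.5344
434,51.8989
435,52.2638
436,52.6292
437,52.9949
438,53.3612
439,53.7282
440,54.0958
441,54.4642
442,54.8336
443,55.2039
444,55.5754
445,55.9481
446,56.3221
447,56.6977
448,57.0748
449,57.4538
450,57.8347
451,58.2176
452,58.6028
453,58.9904
454,59.3806
455,59.7735
456,60.1694
457,60.5683
458,60.9706
459,61.3763
460,61.7857
461,62.199
462,62.6163
463,63.0378
464,63.4639
465,63.8945
466,64.33
467,64.7705
468,65.2162
469,65.6673
470,66.1239
471,66.5863
472,67.0546
473,67.529
474,68.0096
475,68.4966
476,68.9901
477,69.4902
478,69.9971
479,70.5109
480,71.0317
481,71.5595
482,72.0944
483,72.6365
484,73.1858
485,73.7423
486,74.3061
487,74.877
488,75.4552
489,76.0405
490,76.6329
491,77.2323
492,77.8386
493,78.4515
494,79.0711
495,79.6971
496,80.3293
497,80.9674
498,81.6113
499,82.2607
500,82.9152
501,83.5747
502,84.2386
503,84.9067
504,85.5785
505,86.2537
506,86.9318
507,87.6124
508,88.295
509,88.9791
510,89.6642
511,90.3497
512,91.0351
513,91.7198
514,92.4031
515,93.0846
516,93.7636
517,94.4393
518,95.1113
519,95.7787
520,96.441
521,97.0974
522,97.7473
523,98.3899
524,99.0246
525,99.6506
526,100.2673
527,100.8739
528,101.4697
529,102.0541
530,102.6263
531,103.1856
532,103.7314
533,104.263
534,104.7797
535,105.2809
536,105.766
537,106.2343
538,106.6853
539,107.1184
540,107.5331
541,107.9288
542,108.3051
543,108.6614
544,108.9973
545,109.3125
546,109.6064
547,109.8789
548,110.1295
549,110.358
550,110.5641
551,110.7476
552,110.9083
553,111.0461
554,111.1608
555,111.2525
556,111.321
557,111.3664
558,111.3886
559,111.3879
560,111.3643
561,111.3179
562,111.2489
563,111.1576
564,111.0443
565,110.9091
566,110.7525
567,110.5747
568,110.3763
569,110.1576
570,109.919
571,109.6611
572,109.3843
573,109.0892
574,108.7764
575,108.4463
576,108.0997
577,107.7372
578,107.3593
579,106.9668
580,106.5602
581,106.1404
582,105.708
583,105.2637
584,104.8082
585,104.3423
586,103.8666
587,103.3819
588,102.8889
589,102.3884
590,101.8811
591,101.3677
592,100.849
593,100.3256
594,99.7983
595,99.2677
596,98.7346
597,98.1996
598,97.6633
599,97.1266
600,96.5899
601,96.0538
602,95.5191
603,94.9862
604,94.4558
605,93.9283
606,93.4044
607,92.8844
608,92.369
609,91.8585
610,91.3533
611,90.854
612,90.3609
613,89.8743
614,89.3946
615,88.9221
616,88.4572
617,88.0001
618,87.5511
619,87.1103
620,86.6781
621,86.2545
622,85.8399
623,85.4342
624,85.0376
625,84.6503
626,84.2724
627,83.9038
628,83.5446
629,83.1949
630,82.8548
631,82.524
632,82.2028
633,81.891
634,81.5885
635,81.2954
636,81.0115
637,80.7368
638,80.4711
639,80.2144
640,79.9665
641,79.7273
642,79.4967
643,79.2744
644,79.0605
645,78.8546
646,78.6567
647,78.4666
648,78.2841
649,78.1089
650,77.9411
651,77.7802
652,77.6263
653,77.479
654,77.3382
655,77.2037
656,77.0754
657,76.9529
658,76.8362
659,76.725
660,76.6192
661,76.5185
662,76.4229
663,76.332
664,76.2458
665,76.164
666,76.0865
667,76.0131
668,75.9437
669,75.878
670,75.816
671,75.7574
672,75.7021
673,75.6501
674,75.601
675,75.5548
676,75.5114
677,75.4706
678,75.4322
679,75.3963
680,75.3626
681,75.331
682,75.3015
683,75.2739
684,75.2481
685,75.2241
686,75.2016
687,75.1807
688,75.1613
689,75.1432
690,75.1265
691,75.1109
692,75.0965
693,75.0832
694,75.0709
695,75.0595
696,75.0491
697,75.0394
698,75.0306
699,75.0224
700,75.015
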
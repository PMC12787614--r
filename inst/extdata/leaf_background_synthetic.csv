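wavelength,reflectance
300,0.045
301,0.045
302,0.045
303,0.045
304,0.045
305,0.045
306,0.045
307,0.045
308,0.045
309,0.045
310,0.045
311,0.045
312,0.045
313,0.045
314,0.045
315,0.045
316,0.045
317,0.045
318,0.045
319,0.045
320,0.045
321,0.045
322,0.045
323,0.045
324,0.045
325,0.045
326,0.045
327,0.045
328,0.045
329,0.045
330,0.045
331,0.045
332,0.045
333,0.045
334,0.045
335,0.045
336,0.045
337,0.045
338,0.045
339,0.045
340,0.045
341,0.045
342,0.045
343,0.045
344,0.045
345,0.045
346,0.045
347,0.045
348,0.045
349,0.045
350,0.045
351,0.045
352,0.045
353,0.045
354,0.045
355,0.045
356,0.045
357,0.045
358,0.045
359,0.045
360,0.045
361,0.045
362,0.045
363,0.045
364,0.045
365,0.045
366,0.045
367,0.045
368,0.045
369,0.045
370,0.045
371,0.045
372,0.045
373,0.045
374,0.045
375,0.045
376,0.045
377,0.045
378,0.045
379,0.045
380,0.045
381,0.045
382,0.045
383,0.045
384,0.045
385,0.045
386,0.045
387,0.045
388,0.045
389,0.045
390,0.045
391,0.045
392,0.045
393,0.045
394,0.045
395,0.045
396,0.045
397,0.045
398,0.045
399,0.045
400,0.045
401,0.045
402,0.045
403,0.045
404,0.045
405,0.045
406,0.045
407,0.045
408,0.045
409,0.045
410,0.045
411,0.045
412,0.045
413,0.045
414,0.045
415,0.045
416,0.045
417,0.045
418,0.045
419,0.045
420,0.045
421,0.045
422,0.045
423,0.045
424,0.045
425,0.045
426,0.04501
427,0.04501
428,0.04501
429,0.04501
430,0.04501
431,0.04501
432,0.04501
433,0.04502
434,0.04502
435,0.04502
436,0.04503
437,0.04503
438,0.04503
439,0.04504
440,0.04504
441,0.04505
442,0.04506
443,0.04507
444,0.04508
445,0.04509
446,0.0451
447,0.04511
448,0.04513
449,0.04514
450,0.04516
451,0.04519
452,0.04521
453,0.04524
454,0.04527
455,0.0453
456,0.04534
457,0.04538
458,0.04543
459,0.04548
460,0.04554
461,0.0456
462,0.04567
463,0.04575
464,0.04584
465,0.04593
466,0.04603
467,0.04615
468,0.04627
469,0.04641
470,0.04656
471,0.04672
472,0.0469
473,0.04709
474,0.0473
475,0.04753
476,0.04777
477,0.04804
478,0.04833
479,0.04864
480,0.04898
481,0.04934
482,0.04972
483,0.05014
484,0.05059
485,0.05106
486,0.05157
487,0.05211
488,0.05269
489,0.05331
490,0.05396
491,0.05465
492,0.05538
493,0.05616
494,0.05697
495,0.05783
496,0.05874
497,0.05969
498,0.06068
499,0.06173
500,0.06282
501,0.06395
502,0.06514
503,0.06637
504,0.06765
505,0.06898
506,0.07035
507,0.07176
508,0.07322
509,0.07473
510,0.07627
511,0.07785
512,0.07947
513,0.08113
514,0.08281
515,0.08453
516,0.08627
517,0.08804
518,0.08982
519,0.09162
520,0.09343
521,0.09525
522,0.09707
523,0.09889
524,0.10071
525,0.10251
526,0.1043
527,0.10607
528,0.10781
529,0.10952
530,0.1112
531,0.11283
532,0.11442
533,0.11595
534,0.11743
535,0.11885
536,0.1202
537,0.12148
538,0.12268
539,0.12381
540,0.12485
541,0.1258
542,0.12667
543,0.12744
544,0.12811
545,0.12868
546,0.12915
547,0.12952
548,0.12979
549,0.12995
550,0.13
551,0.12995
552,0.12979
553,0.12952
554,0.12915
555,0.12868
556,0.12811
557,0.12744
558,0.12667
559,0.1258
560,0.12485
561,0.12381
562,0.12268
563,0.12148
564,0.1202
565,0.11885
566,0.11743
567,0.11595
568,0.11442
569,0.11283
570,0.1112
571,0.10952
572,0.10781
573,0.10607
574,0.1043
575,0.10251
576,0.10071
577,0.09889
578,0.09707
579,0.09525
580,0.09343
581,0.09162
582,0.08982
583,0.08804
584,0.08627
585,0.08453
586,0.08281
587,0.08113
588,0.07947
589,0.07785
590,0.07627
591,0.07473
592,0.07322
593,0.07176
594,0.07035
595,0.06898
596,0.06765
597,0.06637
598,0.06514
599,0.06395
600,0.06282
601,0.06173
602,0.06068
603,0.05969
604,0.05874
605,0.05783
606,0.05697
607,0.05616
608,0.05538
609,0.05465
610,0.05396
611,0.05331
612,0.05269
613,0.05211
614,0.05157
615,0.05106
616,0.05059
617,0.05014
618,0.04972
619,0.04934
620,0.04898
621,0.04864
622,0.04833
623,0.04804
624,0.04777
625,0.04753
626,0.0473
627,0.04709
628,0.0469
629,0.04672
630,0.04656
631,0.04641
632,0.04627
633,0.04615
634,0.04603
635,0.04593
636,0.04584
637,0.04575
638,0.04567
639,0.0456
640,0.04554
641,0.04548
642,0.04543
643,0.04539
644,0.04535
645,0.04531
646,0.04528
647,0.04525
648,0.04522
649,0.0452
650,0.04518
651,0.04517
652,0.04516
653,0.04514
654,0.04514
655,0.04513
656,0.04513
657,0.04513
658,0.04513
659,0.04514
660,0.04515
661,0.04516
662,0.04518
663,0.0452
664,0.04523
665,0.04526
666,0.0453
667,0.04535
668,0.04541
669,0.04548
670,0.04556
671,0.04566
672,0.04577
673,0.04591
674,0.04606
675,0.04625
676,0.04647
677,0.04673
678,0.04703
679,0.04737
680,0.04778
681,0.04825
682,0.04879
683,0.04942
684,0.05014
685,0.05096
686,0.05189
687,0.05294
688,0.05412
689,0.05543
690,0.05687
691,0.05845
692,0.06015
693,0.06196
694,0.06388
695,0.06587
696,0.06792
697,0.07
698,0.07208
699,0.07413
700,0.07612
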
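# Molar extinction coefficients of oxy- and deoxy-haemoglobin, 450-650 nm.
# Base-10 molar extinction, units cm^-1 M^-1 (per haem group), transcribed
# approximately from standard published compilations of haemoglobin
# absorption spectra.  Values reproduce the characteristic structure
# (HbO2 double peak at ~542/577 nm, Hbr single peak at ~555 nm, isosbestic
# points near 500, 522, 548, 569 and 586 nm) at ~5 nm resolution; they are
# interpolated with a monotone spline at load time.
lambda_nm,eps10_hbo2,eps10_hbr
450,62816,103292
455,50000,90000
460,35000,76000
465,28000,62000
470,24000,50000
475,20500,40000
480,17500,33000
485,15500,27500
490,14500,23800
495,16000,21800
500,20000,20800
505,22500,20400
510,24500,20200
515,27500,20800
520,31500,22000
525,37000,24500
530,43500,28000
535,49500,33500
540,53200,40500
545,52500,46500
550,47500,50500
555,38500,53400
560,29500,53700
565,29000,50500
570,38500,45500
575,53500,40500
580,50500,37000
585,36000,34500
590,17500,30500
595,8500,25000
600,3800,17500
605,2000,12000
610,1300,9500
615,950,8000
620,750,7000
625,650,6200
630,600,5500
635,560,5000
640,520,4600
645,480,4100
650,450,3700
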
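85
-17.000 -75.000
-17.000 -67.500
-17.000 -60.000
-17.000 -52.500
-17.000 -45.000
-14.500 -43.000
-11.000 -41.500
-10.000 -39.000
-13.000 -37.200
-14.195 -36.539
-9.952 -32.297
-7.124 -29.468
-5.002 -27.347
-3.588 -25.933
-2.527 -24.872
4.669 -24.560
11.477 -22.210
17.333 -18.016
21.750 -12.327
24.361 -5.614
24.951 1.564
23.469 8.613
20.040 14.947
14.947 20.040
8.613 23.469
1.564 24.951
-5.614 24.361
-12.327 21.750
-18.016 17.333
-22.210 11.477
-24.560 4.669
-24.872 -2.527
-26.640 -4.295
-29.468 -7.124
-32.297 -9.952
-36.539 -14.195
-40.000 -17.000
-44.000 -13.000
-47.000 -7.000
-49.000 0.000
-50.000 5.000
-50.800 -2.000
-50.500 -9.000
-50.000 -16.000
-49.400 -22.000
-48.800 -27.000
-48.300 -31.000
-47.900 -35.000
-47.600 -38.000
-47.300 -40.500
-47.000 -42.000
-47.000 -45.000
-47.000 -48.000
-47.000 -51.000
-47.000 -54.000
-47.000 -57.000
-47.000 -60.000
-47.000 -63.000
-47.000 -66.000
-47.000 -69.000
-47.000 -72.000
-47.000 -75.000
-45.000 -76.000
-43.143 -76.000
-41.286 -76.000
-39.429 -76.000
-37.571 -76.000
-35.714 -76.000
-33.857 -76.000
-32.000 -76.000
-30.143 -76.000
-28.286 -76.000
-26.429 -76.000
-24.571 -76.000
-22.714 -76.000
-20.857 -76.000
-19.000 -76.000
-16.634 23.755
-12.583 26.128
-8.202 27.816
-3.606 28.775
1.084 28.980
5.746 28.425
10.258 27.125
14.500 25.115
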
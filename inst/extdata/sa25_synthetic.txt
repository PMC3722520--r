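# SA SA25-synthetic 25
> A
2.077671 0.128362 -2.250000
-0.621720 2.393420 -0.750000
-2.383622 -0.658285 0.750000
0.927671 -1.863497 2.250000
> B
-4.862467 -1.575171 -0.000000
-1.062467 -1.575171 -0.000000
1.062467 1.575171 -0.000000
4.862467 1.575171 0.000000
> C
-3.625540 -1.791744 0.907446
0.148900 -1.791744 0.907446
2.146040 1.333375 0.907446
1.330600 2.250113 -2.722338
> D
-3.857837 -2.333834 -0.673364
-0.040864 -2.333834 -0.673364
1.687939 1.012689 -0.673364
2.210761 3.654980 2.020092
> E
-3.756746 -2.395859 0.729666
0.089648 -2.395859 0.729666
1.245813 1.314508 0.729666
2.421285 3.477210 -2.188998
> F
-3.408857 -1.885053 -0.823870
0.373476 -1.885053 -0.823870
2.340612 1.257809 -0.823870
0.694769 2.512298 2.471611
> G
-2.955556 -2.510554 -0.139816
0.864072 -2.510554 -0.139816
2.233018 1.072081 -0.139816
-0.141534 3.949027 0.419447
> H
-3.653974 -2.197206 -0.449399
0.130696 -2.197206 -0.449399
0.253124 1.565000 -0.449399
3.270154 2.829412 1.348197
> I
-1.607967 -2.041631 0.332289
2.133388 -2.041631 0.332289
1.543094 1.775856 0.332289
-2.068515 2.307406 -0.996867
> J
-4.086739 -1.551234 -0.482564
-0.234601 -1.551234 -0.482564
0.655008 2.108795 -0.482564
3.666331 0.993673 1.447693
> K
-2.596789 -2.328182 -0.809362
1.257550 -2.328182 -0.809362
0.917203 1.377730 -0.809362
0.422036 3.278634 2.428085
> L
-3.547165 -1.828792 0.749280
0.309071 -1.828792 0.749280
0.513982 2.017371 0.749280
2.724112 1.640212 -2.247841
> M
-4.547260 -1.984787 0.591954
-0.753224 -1.984787 0.591954
2.009060 0.676400 0.591954
3.291425 3.293174 -1.775863
> N
-4.760758 -0.816905 -0.375748
-1.056941 -0.816905 -0.375748
1.506955 1.934763 -0.375748
4.310743 -0.300952 1.127245
> O
-4.838457 -1.211799 0.644315
-1.008737 -1.211799 0.644315
1.621081 1.578495 0.644315
4.226113 0.845103 -1.932944
> P
-2.618330 -1.919728 0.374199
1.256785 -1.919728 0.374199
2.419430 1.628098 0.374199
-1.057885 2.211359 -1.122597
> Q
-2.054295 -2.426722 -0.225544
1.789123 -2.426722 -0.225544
1.545114 1.277852 -0.225544
-1.279942 3.575591 0.676632
> R
-3.107601 -2.684427 -0.280270
0.708642 -2.684427 -0.280270
0.118716 1.165406 -0.280270
2.280243 4.203448 0.840811
> S
-2.884156 -2.115085 -0.351679
0.869447 -2.115085 -0.351679
2.511656 1.253272 -0.351679
-0.496948 2.976898 1.055036
> T
-4.958416 -1.220551 -0.474335
-1.192777 -1.220551 -0.474335
1.453866 1.441627 -0.474335
4.697328 0.999475 1.423004
> U
-3.649150 -1.831637 -0.015667
0.062539 -1.831637 -0.015667
-0.125962 2.042333 -0.015667
3.712573 1.620941 0.047002
> V
-2.079682 -2.075925 -0.128072
1.776108 -2.075925 -0.128072
1.992403 1.780691 -0.128072
-1.688828 2.371160 0.384217
> W
-3.000247 -1.981073 -0.882364
0.779254 -1.981073 -0.882364
0.437866 1.731249 -0.882364
1.783127 2.230898 2.647092
> X
-2.812937 -2.301698 0.868297
0.918369 -2.301698 0.868297
1.277991 1.538541 0.868297
0.616577 3.064855 -2.604892
> Y
-4.447181 -1.230918 0.397474
-0.648940 -1.230918 0.397474
1.048288 2.074611 0.397474
4.047833 0.387226 -1.192423
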
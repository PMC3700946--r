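tag,site,ccl_cm,track_start,track_end,tracking_days,internest_start,internest_end,internesting_days,encounters,mean_interval_d,mean_distance_km,n_distances,tdm_km,tdm_per_day
108170,AL,95.2,2011-06-06,2011-08-31,86,,,NA,1,NA,NA,NA,NA,NA
106360,AL,92.3,2011-06-07,2011-08-31,85,2011-06-07,2011-08-04,58,3,22.5,7.1,2,836.0,14.4
108172,AL,93.9,2011-06-08,2011-08-31,84,2011-06-08,2011-08-31,84,3,22,129.0,2,2683.4,31.9
106345,AL,90.1,2011-06-09,2011-08-31,83,2011-06-09,2011-08-31,83,2,42,3.5,2,2163.4,26.1
108171,AL,90.4,2011-06-09,2011-08-31,83,,,NA,1,NA,NA,NA,NA,NA
106337,AL,93.6,2011-06-11,2011-08-31,81,2011-06-11,2011-08-31,81,3,21.5,8.7,2,1800.0,22.2
108173,AL,95.9,2011-06-11,2011-08-31,81,,,NA,1,NA,NA,NA,NA,NA
108174,AL,88.0,2011-06-13,2011-07-11,28,,,NA,1,NA,NA,NA,NA,NA
106358,AL,92.5,2011-06-14,2011-08-31,78,,,NA,1,NA,NA,NA,NA,NA
106361,AL,92.0,2011-06-15,2011-08-31,77,,,NA,1,NA,NA,NA,NA,NA
108961,AL,91.5,2011-07-23,2011-08-31,39,,,NA,1,NA,NA,NA,NA,NA
108964,AL,94.6,2011-07-30,2011-08-31,32,,,NA,1,NA,NA,NA,NA,NA
108965,AL,87.0,2011-07-31,2011-08-31,31,,,NA,1,NA,NA,NA,NA,NA
119940,AL,94.2,2012-06-01,2012-08-08,68,2012-06-01,2012-08-07,67,3,19.5,13.0,2,2619.3,39.1
119941,AL,92.0,2012-06-03,2012-08-28,86,2012-06-03,2012-07-26,23,2,19,118.7,1,2110.3,39.8
119943,AL,97.5,2012-06-04,2012-08-31,88,2012-06-04,2012-08-29,86,1,NA,NA,NA,2230.4,25.9
119938,AL,97.5,2012-06-04,2012-08-31,88,,,NA,1,NA,NA,NA,NA,NA
119924,AL,95.4,2012-06-05,2012-08-31,87,2012-06-06,2012-08-31,86,2,12,7.8,1,2897.8,33.7
119944,AL,90.8,2012-06-07,2012-08-31,85,2012-06-07,2012-08-29,83,1,NA,NA,NA,1324.6,16.0
119946,AL,95.0,2012-06-09,2012-08-31,83,2012-06-09,2012-08-29,81,2,13,254.6,1,1220.4,15.1
119945,AL,98.9,2012-06-09,2012-08-08,60,,,NA,1,NA,NA,NA,NA,NA
119947,AL,98.5,2012-06-13,2012-08-12,60,2012-06-13,2012-08-12,60,1,NA,NA,NA,725.1,12.1
119923,AL,95.6,2012-06-13,2012-08-31,79,2012-06-13,2012-08-31,79,2,12,12.9,1,2491.1,31.5
57656,SJP,99.5,2010-07-26,2010-08-31,36,,,NA,2,24,1.7,1,NA,NA
89971,SJP,103.2,2010-07-27,2010-08-31,35,,,NA,5,14,2.2,4,NA,NA
47755,SJP,97.2,2010-08-03,2010-08-31,28,,,NA,3,12,0.2,2,NA,NA
52968,SJP,90.0,2010-08-04,2010-08-31,27,,,NA,1,NA,NA,NA,NA,NA
53017,SJP,88.0,2012-06-03,2012-06-29,26,2012-06-03,2012-06-26,23,2,26,2.0,1,293.1,12.7
53016,SJP,102.0,2012-06-04,2012-08-10,67,2012-06-04,2012-07-17,43,4,13,4.4,3,515.4,12.0
53000,SJP,102.0,2012-06-08,2012-08-27,80,2012-06-08,2012-08-27,80,1,NA,NA,NA,1638.7,20.5
53164,SJP,102.0,2012-06-08,2012-07-21,43,2012-06-08,2012-07-14,36,5,11.8,2.4,4,220.8,6.1
119942,SJP,82.4,2012-06-10,2012-08-31,82,2012-06-10,2012-08-31,82,3,21,1.4,2,2221.0,27.1
119950,SJP,102.0,2012-06-11,2012-08-06,56,2012-06-11,2012-08-05,55,4,17.3,3.0,3,540.4,9.8
119949,SJP,100.0,2012-06-11,2012-07-21,40,2012-06-11,2012-07-12,31,4,13,1.7,3,399.4,12.9
119951,SJP,103.3,2012-06-11,2012-08-02,52,2012-06-11,2012-07-18,37,1,NA,NA,NA,422.0,11.4
119948,SJP,92.5,2012-06-11,2012-08-31,81,,,NA,5,12.8,1.7,4,NA,NA
119952a,SJP,101.1,2012-06-13,2012-07-06,23,2012-06-13,2012-07-06,23,2,23,402.1,1,653.3,28.4
119952,SJP,90.1,2012-07-23,2012-08-31,39,2012-07-23,2012-08-29,37,3,11.5,1.8,2,752.5,20.3
120438,EAFB,97.0,2012-07-10,2012-08-31,52,2012-07-10,2012-08-31,52,1,NA,NA,NA,2837.3,54.6
120439,EAFB,102.5,2012-07-11,2012-08-31,51,2012-07-11,2012-08-02,22,2,22,54.8,1,531.7,24.2
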
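equation,creatinine_mgdl,cystatin_mgl,age,sex,expected_gfr
CKDEPI_CR_2009,0.6,,25,male,139.7409954082
CKDEPI_CYS_2012,,0.6,25,male,138.8927353972
CKDEPI_CRCYS_2012,0.6,0.6,25,male,144.2825150189
CKDEPI_CR_2021,0.6,,25,male,137.3860745443
CKDEPI_CRCYS_2021,0.6,0.6,25,male,142.4359525142
EKFC_CR,0.6,,25,male,122.2647058592
EKFC_CYS,,0.6,25,male,119.1182117763
EKFC_CRCYS,0.6,0.6,25,male,120.6914588178
CKDEPI_CR_2009,0.9,,25,male,118.2906246197
CKDEPI_CYS_2012,,0.8,25,male,120.3192459668
CKDEPI_CRCYS_2012,0.9,0.8,25,male,119.0997327981
CKDEPI_CR_2021,0.9,,25,male,121.5522926359
CKDEPI_CRCYS_2021,0.9,0.8,25,male,122.4354751403
EKFC_CR,0.9,,25,male,107.3000000000
EKFC_CYS,,0.8,25,male,108.5795136175
EKFC_CRCYS,0.9,0.8,25,male,107.9397568088
CKDEPI_CR_2009,1.8,,25,male,51.1687797554
CKDEPI_CYS_2012,,1.6,25,male,47.9255678460
CKDEPI_CRCYS_2012,1.8,1.6,25,male,47.9688639131
CKDEPI_CR_2021,1.8,,25,male,52.9087084120
CKDEPI_CRCYS_2021,1.8,1.6,25,male,48.9717492028
EKFC_CR,1.8,,25,male,48.9591384604
EKFC_CYS,,1.6,25,male,51.0425428650
EKFC_CRCYS,1.8,1.6,25,male,50.0008406627
CKDEPI_CR_2009,0.6,,50,male,117.2343945519
CKDEPI_CYS_2012,,0.6,50,male,125.6501443102
CKDEPI_CRCYS_2012,0.6,0.6,50,male,127.2889554532
CKDEPI_CR_2021,0.6,,50,male,117.6027629374
CKDEPI_CRCYS_2021,0.6,0.6,50,male,129.1793594306
EKFC_CR,0.6,,50,male,110.5740083853
EKFC_CYS,,0.6,50,male,107.7283755376
EKFC_CRCYS,0.6,0.6,50,male,109.1511919615
CKDEPI_CR_2009,0.9,,50,male,99.2388076094
CKDEPI_CYS_2012,,0.8,50,male,108.8475259399
CKDEPI_CRCYS_2012,0.9,0.8,50,male,105.0721952043
CKDEPI_CR_2021,0.9,,50,male,104.0490129932
CKDEPI_CRCYS_2021,0.9,0.8,50,male,111.0403375764
EKFC_CR,0.9,,50,male,97.0401966484
EKFC_CYS,,0.8,50,male,98.1973658288
EKFC_CRCYS,0.9,0.8,50,male,97.6187812386
CKDEPI_CR_2009,1.8,,50,male,42.9275667964
CKDEPI_CYS_2012,,1.6,50,male,43.3561517726
CKDEPI_CRCYS_2012,1.8,1.6,50,male,42.3191027754
CKDEPI_CR_2021,1.8,,50,male,45.2899634358
CKDEPI_CRCYS_2021,1.8,1.6,50,male,44.4139213489
EKFC_CR,1.8,,50,male,44.2777672314
EKFC_CYS,,1.6,50,male,46.1619608300
EKFC_CRCYS,1.8,1.6,50,male,45.2198640307
CKDEPI_CR_2009,0.6,,80,male,94.9582057052
CKDEPI_CYS_2012,,0.6,80,male,111.4148665509
CKDEPI_CRCYS_2012,0.6,0.6,80,male,109.5174050773
CKDEPI_CR_2021,0.6,,80,male,97.5859506829
CKDEPI_CRCYS_2021,0.6,0.6,80,male,114.8897619552
EKFC_CR,0.6,,80,male,81.7916352897
EKFC_CYS,,0.6,80,male,84.0654611366
EKFC_CRCYS,0.6,0.6,80,male,82.9285482132
CKDEPI_CR_2009,0.9,,80,male,80.3820341542
CKDEPI_CYS_2012,,0.8,80,male,96.5158666834
CKDEPI_CRCYS_2012,0.9,0.8,80,male,90.4024557635
CKDEPI_CR_2021,0.9,,80,male,86.3391437153
CKDEPI_CRCYS_2021,0.9,0.8,80,male,98.7572473483
EKFC_CR,0.9,,80,male,71.7806696945
EKFC_CYS,,0.8,80,male,76.6279710393
EKFC_CRCYS,0.9,0.8,80,male,74.2043203669
CKDEPI_CR_2009,1.8,,80,male,34.7707235053
CKDEPI_CYS_2012,,1.6,80,male,38.4442046639
CKDEPI_CRCYS_2012,1.8,1.6,80,male,36.4106870440
CKDEPI_CR_2021,1.8,,80,male,37.5812950979
CKDEPI_CRCYS_2021,1.8,1.6,80,male,39.5009301313
EKFC_CR,1.8,,80,male,32.7522809539
EKFC_CYS,,1.6,80,male,41.2108529386
EKFC_CRCYS,1.8,1.6,80,male,36.9815669463
CKDEPI_CR_2009,0.5,,25,female,134.5160874161
CKDEPI_CYS_2012,,0.6,25,female,129.4480293902
CKDEPI_CRCYS_2012,0.5,0.6,25,female,139.7418032845
CKDEPI_CR_2021,0.5,,25,female,133.4014418834
CKDEPI_CRCYS_2021,0.5,0.6,25,female,139.2806579938
EKFC_CR,0.5,,25,female,119.5784581904
EKFC_CYS,,0.6,25,female,119.1182117763
EKFC_CRCYS,0.5,0.6,25,female,119.3483349834
CKDEPI_CR_2009,0.7,,25,female,120.4198558629
CKDEPI_CYS_2012,,0.8,25,female,112.1375372410
CKDEPI_CRCYS_2012,0.7,0.8,25,female,115.4076410813
CKDEPI_CR_2021,0.7,,25,female,123.0109201475
CKDEPI_CRCYS_2021,0.7,0.8,25,female,117.9053625601
EKFC_CR,0.7,,25,female,107.3000000000
EKFC_CYS,,0.8,25,female,108.5795136175
EKFC_CRCYS,0.7,0.8,25,female,107.9397568088
CKDEPI_CR_2009,1.6,,25,female,44.3241661722
CKDEPI_CYS_2012,,1.6,25,female,44.6666292325
CKDEPI_CRCYS_2012,1.6,1.6,25,female,42.8973090516
CKDEPI_CR_2021,1.6,,25,female,45.6160142836
CKDEPI_CRCYS_2021,1.6,1.6,25,female,43.8555219999
EKFC_CR,1.6,,25,female,42.0907711804
EKFC_CYS,,1.6,25,female,51.0425428650
EKFC_CRCYS,1.6,1.6,25,female,46.5666570227
CKDEPI_CR_2009,0.5,,50,female,112.8510071053
CKDEPI_CYS_2012,,0.6,50,female,117.1059344971
CKDEPI_CRCYS_2012,0.5,0.6,50,female,123.2830476437
CKDEPI_CR_2021,0.5,,50,female,114.1919091680
CKDEPI_CRCYS_2021,0.5,0.6,50,female,126.3177299209
EKFC_CR,0.5,,50,female,108.1446141446
EKFC_CYS,,0.6,50,female,107.7283755376
EKFC_CRCYS,0.5,0.6,50,female,107.9364948411
CKDEPI_CR_2009,0.7,,50,female,101.0251061464
CKDEPI_CYS_2012,,0.8,50,female,101.4458941760
CKDEPI_CRCYS_2012,0.7,0.8,50,female,101.8149571529
CKDEPI_CR_2021,0.7,,50,female,105.2976011491
CKDEPI_CRCYS_2021,0.7,0.8,50,female,106.9318450861
EKFC_CR,0.7,,50,female,97.0401966484
EKFC_CYS,,0.8,50,female,98.1973658288
EKFC_CRCYS,0.7,0.8,50,female,97.6187812386
CKDEPI_CR_2009,1.6,,50,female,37.1853425692
CKDEPI_CYS_2012,,1.6,50,female,40.4079334521
CKDEPI_CRCYS_2012,1.6,1.6,50,female,37.8448744133
CKDEPI_CR_2021,1.6,,50,female,39.0474022330
CKDEPI_CRCYS_2021,1.6,1.6,50,female,39.7738642487
EKFC_CR,1.6,,50,female,38.0661389789
EKFC_CYS,,1.6,50,female,46.1619608300
EKFC_CRCYS,1.6,1.6,50,female,42.1140499044
CKDEPI_CR_2009,0.5,,80,female,91.4077237120
CKDEPI_CYS_2012,,0.6,80,female,103.8386556254
CKDEPI_CRCYS_2012,0.5,0.6,80,female,106.0707853237
CKDEPI_CR_2021,0.5,,80,female,94.7556480658
CKDEPI_CRCYS_2021,0.5,0.6,80,female,112.3446809560
EKFC_CR,0.5,,80,female,79.9946114627
EKFC_CYS,,0.6,80,female,84.0654611366
EKFC_CRCYS,0.5,0.6,80,female,82.0300362997
CKDEPI_CR_2009,0.7,,80,female,81.8289107689
CKDEPI_CYS_2012,,0.8,80,female,89.9527877489
CKDEPI_CRCYS_2012,0.7,0.8,80,female,87.5999796349
CKDEPI_CR_2021,0.7,,80,female,87.3752134398
CKDEPI_CRCYS_2021,0.7,0.8,80,female,95.1032291964
EKFC_CR,0.7,,80,female,71.7806696945
EKFC_CYS,,0.8,80,female,76.6279710393
EKFC_CRCYS,0.7,0.8,80,female,74.2043203669
CKDEPI_CR_2009,1.6,,80,female,30.1196028896
CKDEPI_CYS_2012,,1.6,80,female,35.8299987467
CKDEPI_CRCYS_2012,1.6,1.6,80,female,32.5611316902
CKDEPI_CR_2021,1.6,,80,female,32.4012614451
CKDEPI_CRCYS_2021,1.6,1.6,80,female,35.3741481280
EKFC_CR,1.6,,80,female,28.1575372161
EKFC_CYS,,1.6,80,female,41.2108529386
EKFC_CRCYS,1.6,1.6,80,female,34.6841950774
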
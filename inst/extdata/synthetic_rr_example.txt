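0.84229518
0.87367370
0.87078387
0.84866876
0.87909906
0.87516583
0.87835810
0.83174857
0.83728737
0.87304028
0.90811707
0.97420780
0.96571075
0.97810028
0.94566230
0.95544612
0.95957642
0.88232945
0.84868235
0.80633516
0.84723206
0.91537704
0.89406014
0.94983979
0.96692263
0.97525746
0.96285353
0.91307994
0.90317614
0.93974221
0.86511452
0.87639917
0.87412069
0.87205065
0.89415961
0.89882514
0.88402566
0.87314131
0.90611400
0.91971708
0.93021376
0.98114615
0.97020543
0.94610749
0.94078331
0.92081656
0.89155540
0.90382134
0.92156655
0.87115194
0.90765689
0.88841789
0.86800542
0.81968416
0.81119793
0.79635391
0.83954358
0.84612205
0.83304404
0.84632639
0.88081379
0.90648728
0.92366775
0.97623818
0.98932796
0.96225464
0.95882437
0.94334370
0.93487336
0.91906659
0.90004298
0.90666066
0.92618107
0.96347975
0.90113985
0.84532721
0.88311180
0.87048857
0.89224551
0.92560926
0.90387953
0.93168480
0.91978564
0.91084219
0.91288702
0.90295395
0.85886232
0.85975044
0.90393914
0.90498526
0.90959385
0.89649285
0.89962614
0.89001190
0.86848058
0.86433204
0.85666050
0.85391710
0.84023645
0.83177808
0.89110560
0.90986728
0.92942074
0.89524158
0.85262023
0.90987733
0.90494613
0.83801924
0.89204575
0.94341877
0.94495075
0.96278121
0.92353489
0.95983204
0.98091696
0.97892305
0.94893519
0.89247963
0.81290976
0.85988437
0.84256949
0.83113558
0.79196580
0.82918140
0.82152949
0.82605498
0.81159188
0.82316629
0.79876448
0.79643941
0.80229850
0.75966739
0.76936106
0.79696925
0.83943912
0.82151453
0.83419821
0.80040683
0.81277423
0.81928591
0.86129312
0.86416801
0.89887705
0.92025709
0.91431043
0.93710894
0.90257063
0.85616129
0.85882741
0.85143910
0.82998239
0.86815498
0.86760074
0.91924574
0.91988395
0.96859509
0.97193729
0.97338576
1.00968379
0.98448326
0.99255556
0.97291213
0.97903652
0.94429194
0.90814198
0.92089977
0.90149022
0.87601632
0.90170248
0.87719743
0.90932148
0.92108303
0.97352515
0.99514117
0.95686944
0.90497526
0.94664320
0.95257846
0.86338224
0.86849092
0.87326459
0.84050167
0.87395545
0.91083322
0.91930621
0.90350212
0.86539933
0.89845660
0.93407917
0.87090270
0.88458611
0.86192488
0.92162264
1.00604595
0.98893116
0.99361932
0.98138732
0.94734303
0.91881414
0.90963391
0.91613019
0.94383298
0.94218134
0.92465481
0.90887997
0.89276052
0.89673067
0.90109995
0.93405638
0.92262748
0.92615714
0.96438199
0.90734720
0.90660916
0.92613801
0.87442132
0.87511056
0.83815834
0.86355120
0.84959667
0.82568738
0.81091041
0.78921401
0.80609255
0.83480838
0.86188145
0.83326351
0.83741843
0.84193274
0.86325106
0.85041185
0.85297862
0.82844740
0.86943522
0.85965281
0.89685562
0.90510807
0.94065650
0.92565711
0.90816656
0.95264854
0.96897633
0.95063175
0.94469985
0.89339388
0.87735071
0.84396813
0.84577069
0.90213736
0.85533575
0.80957718
0.82321323
0.79656245
0.76376818
0.77065713
0.79667310
0.81513785
0.90792530
0.97406464
0.94617207
0.93762132
0.96594395
0.96372290
0.93988966
0.96683366
0.92291007
0.82754988
0.85512193
0.79944214
0.75565435
0.78526030
0.82623057
0.83393561
0.81204128
0.88986598
0.94788780
0.94719011
0.96775475
1.01325274
0.97947763
0.99628732
0.96574913
0.92107791
0.90794062
0.92652871
0.89690648
0.88150403
0.84974863
0.91169279
0.93542567
0.96602354
0.91915614
0.86416204
0.87089207
0.94204793
0.92711380
0.91876467
0.88124737
0.86962177
0.87786150
0.96251249
0.97992029
0.94894147
0.91929017
0.90209125
0.92125881
0.87887828
0.89250599
0.89654869
0.95532132
0.93660878
0.92828306
0.93994442
0.92720026
0.94442008
0.95393571
0.90355700
0.86249910
0.88099607
0.89400946
0.95282467
0.92305592
0.96440397
0.93916806
0.90381203
0.90220027
0.89997154
0.92034160
0.97774460
0.97944263
0.92755404
0.92178422
0.90292059
0.92231237
0.91732153
0.92790975
0.88293693
0.82856882
0.84328090
0.88740533
0.88301120
0.82713427
0.85839961
0.86007655
0.88190693
0.95291901
0.99206216
0.97746103
0.96535917
0.99339185
0.94505868
0.97604585
0.92991751
0.95709515
0.96277125
0.92740185
0.89181163
0.89943103
0.87404743
0.86901046
0.83643974
0.89986789
0.91990775
0.93496329
0.89372090
0.95443328
0.97389471
0.99826030
0.98397880
0.97192750
0.99434946
1.00951696
0.96085718
0.87357137
0.90148386
0.89347314
0.84429871
0.91229570
0.90194599
0.92364205
0.93690974
0.91344315
0.91053953
0.94516743
0.89982314
0.92284708
0.87537017
0.84425466
0.88681736
0.88484468
0.88042278
0.86175564
0.85647942
0.85096218
0.86394926
0.85329493
0.86864607
0.89065723
0.91160710
0.85429046
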
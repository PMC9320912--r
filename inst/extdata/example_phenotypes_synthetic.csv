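genotype,treatment,replicate,trait,value
G01,CK,1,SL,32.8092
G01,CK,2,SL,31.7443
G01,CK,3,SL,32.8046
G01,LT,1,SL,18.1453
G01,LT,2,SL,18.3259
G01,LT,3,SL,17.4442
G02,CK,1,SL,22.1496
G02,CK,2,SL,20.7216
G02,CK,3,SL,21.3093
G02,LT,1,SL,10.813
G02,LT,2,SL,10.3177
G02,LT,3,SL,11.1045
G03,CK,1,SL,26.518
G03,CK,2,SL,26.0708
G03,CK,3,SL,26.9608
G03,LT,1,SL,13.1861
G03,LT,2,SL,12.9348
G03,LT,3,SL,13.6527
G04,CK,1,SL,27.1735
G04,CK,2,SL,29.0754
G04,CK,3,SL,27.485
G04,LT,1,SL,13.8163
G04,LT,2,SL,13.6787
G04,LT,3,SL,13.2325
G01,CK,1,RSR,0.336468
G01,CK,2,RSR,0.327184
G01,CK,3,RSR,0.321801
G01,LT,1,RSR,0.379871
G01,LT,2,RSR,0.384487
G01,LT,3,RSR,0.37775
G02,CK,1,RSR,0.25981
G02,CK,2,RSR,0.286652
G02,CK,3,RSR,0.2811
G02,LT,1,RSR,0.310694
G02,LT,2,RSR,0.314412
G02,LT,3,RSR,0.32222
G03,CK,1,RSR,0.408727
G03,CK,2,RSR,0.434384
G03,CK,3,RSR,0.421971
G03,LT,1,RSR,0.471188
G03,LT,2,RSR,0.469526
G03,LT,3,RSR,0.46672
G04,CK,1,RSR,0.276211
G04,CK,2,RSR,0.28422
G04,CK,3,RSR,0.29037
G04,LT,1,RSR,0.288124
G04,LT,2,RSR,0.291695
G04,LT,3,RSR,0.301695
G01,CK,1,MDA,5.84895
G01,CK,2,MDA,5.79579
G01,CK,3,MDA,5.56588
G01,LT,1,MDA,16.6251
G01,LT,2,MDA,17.9802
G01,LT,3,MDA,17.3161
G02,CK,1,MDA,3.89478
G02,CK,2,MDA,3.8704
G02,CK,3,MDA,3.74777
G02,LT,1,MDA,12.8428
G02,LT,2,MDA,12.5274
G02,LT,3,MDA,12.5403
G03,CK,1,MDA,5.14893
G03,CK,2,MDA,5.13172
G03,CK,3,MDA,5.22026
G03,LT,1,MDA,15.9306
G03,LT,2,MDA,16.478
G03,LT,3,MDA,16.8482
G04,CK,1,MDA,5.81061
G04,CK,2,MDA,5.85434
G04,CK,3,MDA,5.80696
G04,LT,1,MDA,19.505
G04,LT,2,MDA,20.4266
G04,LT,3,MDA,20.7808
G01,CK,1,MSI,78.4076
G01,CK,2,MSI,78.0411
G01,CK,3,MSI,73.3917
G01,LT,1,MSI,68.7395
G01,LT,2,MSI,63.7445
G01,LT,3,MSI,65.2383
G02,CK,1,MSI,79.6086
G02,CK,2,MSI,80.3279
G02,CK,3,MSI,81.0796
G02,LT,1,MSI,64.4298
G02,LT,2,MSI,64.1516
G02,LT,3,MSI,64.4084
G03,CK,1,MSI,80.1259
G03,CK,2,MSI,80.0808
G03,CK,3,MSI,77.3498
G03,LT,1,MSI,64.3685
G03,LT,2,MSI,64.1174
G03,LT,3,MSI,70.607
G04,CK,1,MSI,81.5795
G04,CK,2,MSI,85.332
G04,CK,3,MSI,81.2584
G04,LT,1,MSI,61.964
G04,LT,2,MSI,65.0006
G04,LT,3,MSI,62.8509
G01,CK,1,Pro,29.0361
G01,CK,2,Pro,28.6671
G01,CK,3,Pro,28.5081
G01,LT,1,Pro,120.197
G01,LT,2,Pro,123.116
G01,LT,3,Pro,128.412
G02,CK,1,Pro,23.4833
G02,CK,2,Pro,22.7481
G02,CK,3,Pro,23.0869
G02,LT,1,Pro,97.2651
G02,LT,2,Pro,98.1942
G02,LT,3,Pro,90.9996
G03,CK,1,Pro,23.4912
G03,CK,2,Pro,24.4391
G03,CK,3,Pro,23.2442
G03,LT,1,Pro,96.4269
G03,LT,2,Pro,96.3296
G03,LT,3,Pro,94.0413
G04,CK,1,Pro,33.4602
G04,CK,2,Pro,33.8796
G04,CK,3,Pro,33.4912
G04,LT,1,Pro,136.673
G04,LT,2,Pro,130.291
G04,LT,3,Pro,130.478
G01,CK,1,Put,95.8771
G01,CK,2,Put,90.9656
G01,CK,3,Put,93.7794
G01,LT,1,Put,271.584
G01,LT,2,Put,294.658
G01,LT,3,Put,282.196
G02,CK,1,Put,81.2545
G02,CK,2,Put,79.3985
G02,CK,3,Put,82.3836
G02,LT,1,Put,225.764
G02,LT,2,Put,227.578
G02,LT,3,Put,240.355
G03,CK,1,Put,94.5215
G03,CK,2,Put,92.0145
G03,CK,3,Put,95.4867
G03,LT,1,Put,265.285
G03,LT,2,Put,272.975
G03,LT,3,Put,279.96
G04,CK,1,Put,104.279
G04,CK,2,Put,108.905
G04,CK,3,Put,107.704
G04,LT,1,Put,296.364
G04,LT,2,Put,286.528
G04,LT,3,Put,295.84
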
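anatomical_site,filter,feature_class,feature_name,coefficient
distal_femur,Intercept,Intercept,Intercept,160.0959
distal_femur,original,firstorder,Mean,-0.1090
distal_femur,wavelet_H,glrlm,GrayLevelNonUniformity,1.0751
distal_femur,wavelet_H,gldm,DependenceNonUniformity,0.4234
distal_femur,wavelet_L,firstorder,Mean,-0.1037
distal_femur,wavelet_L,glrlm,RunLengthNonUniformity,0.0001
distal_femur,wavelet_L,glszm,SizeZoneNonUniformity,0.0365
distal_femur,wavelet_L,ngtdm,Complexity,0.5758
proximal_tibia,Intercept,Intercept,Intercept,160.0959
proximal_tibia,original,shape2d,MajorAxisLength,1.8547
proximal_tibia,original,shape2d,MaximumDiameter,-2.4652
proximal_tibia,original,shape2d,Perimeter,1.1009
proximal_tibia,original,firstorder,10Percentile,-1.0655
proximal_tibia,original,firstorder,Range,6.0021
proximal_tibia,original,firstorder,RobustMeanAbsoluteDeviation,1.4276
proximal_tibia,original,firstorder,Variance,-0.0007
proximal_tibia,original,glcm,JointAverage,-0.4492
proximal_tibia,original,glcm,SumAverage,-1.072093e-13
proximal_tibia,original,glrlm,LongRunEmphasis,0.2136
proximal_tibia,original,glrlm,RunLengthNonUniformity,3.8091
proximal_tibia,original,glrlm,ShortRunHighGrayLevelEmphasis,7.7804
proximal_tibia,original,glszm,LargeAreaEmphasis,0.4598
proximal_tibia,original,glszm,SmallAreaHighGrayLevelEmphasis,0.1444
proximal_tibia,original,ngtdm,Complexity,-4.1813
proximal_tibia,wavelet_H,firstorder,Variance,-4.5816
proximal_tibia,wavelet_L,firstorder,InterquartileRange,0.6352
proximal_tibia,wavelet_L,firstorder,Median,-2.3973
proximal_tibia,wavelet_L,firstorder,Minimum,6.3474
proximal_tibia,wavelet_L,glcm,ClusterProminence,-2.8356
proximal_tibia,wavelet_L,glrlm,GrayLevelVariance,-2.3664
proximal_tibia,wavelet_L,glrlm,LongRunEmphasis,0.5052
proximal_tibia,wavelet_L,glrlm,RunLengthNonUniformity,0.7373
proximal_tibia,wavelet_L,glszm,GrayLevelVariance,-0.0729
proximal_tibia,wavelet_L,glszm,LargeAreaEmphasis,0.2385
proximal_tibia,wavelet_L,glszm,SizeZoneNonUniformity,0.2360
proximal_tibia,wavelet_L,ngtdm,Complexity,-0.0861
proximal_tibia,wavelet_L,gldm,DependenceNonUniformity,-1.0041
proximal_tibia,wavelet_L,gldm,SmallDependenceHighGrayLevelEmphasis,-0.8489
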
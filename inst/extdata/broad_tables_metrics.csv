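# Transcription of the published benchmark grid: five classifiers (NB, SVM, KNN, RF, IRF)
# x four reduction strategies (AV = all variables, PCA, SKPCA = single Gaussian-kernel KPCA,
# WKPCA = weighted kernel PCA) x six Broad Institute expression datasets x four metrics.
# "formula" records which kernel-combination preset the WKPCA row used (eq33/eq34/eq35;
# eq36 = single Gaussian kernel for SKPCA rows). n_features is the retained dimension.
# NA rows: naive Bayes on the full variable set fails when a feature has zero variance.
# Amendment: Lung / SVM / WKPCA macro_f1 is printed as 0.9728 in the source table, which
# contradicts the table's own optimum marking (PCA's 0.9675 is marked best), the stated
# per-dataset non-optimal counts (4,14,5,13,10,3) and the published OPR = 71/120. The digits
# are treated as a misprint and the cell is recorded as 0.9628 (below the marked optimum).
dataset,classifier,strategy,formula,n_features,accuracy,macro_recall,macro_precision,macro_f1
Breast,NB,AV,,1213,0.9088,0.8291,0.9179,0.8357
Breast,NB,PCA,,16,0.7500,0.8456,0.8790,0.8609
Breast,NB,SKPCA,eq36,16,0.7449,0.7597,0.7113,0.6937
Breast,NB,WKPCA,eq33,16,0.9290,0.8874,0.9247,0.8921
Breast,SVM,AV,,1213,0.5200,0.6325,0.5200,0.6797
Breast,SVM,PCA,,14,0.8679,0.7244,0.8965,0.8426
Breast,SVM,SKPCA,eq36,14,0.8984,0.8250,0.9180,0.8472
Breast,SVM,WKPCA,eq33,14,0.9184,0.8394,0.9375,0.8625
Breast,KNN,AV,,1213,0.8876,0.7731,0.8887,0.8052
Breast,KNN,PCA,,14,0.9085,0.8287,0.9211,0.8355
Breast,KNN,SKPCA,eq36,14,0.8980,0.8041,0.8754,0.8253
Breast,KNN,WKPCA,eq33,14,0.9290,0.8847,0.9348,0.8955
Breast,RF,AV,,1213,0.8673,0.6889,0.7951,0.6020
Breast,RF,PCA,,15,0.8571,0.6960,0.8051,0.6888
Breast,RF,SKPCA,eq36,15,0.8571,0.6990,0.8070,0.6911
Breast,RF,WKPCA,eq33,15,0.8673,0.7043,0.8215,0.7018
Breast,IRF,AV,,1213,0.9085,0.7937,0.9112,0.8225
Breast,IRF,PCA,,6,0.8374,0.6866,0.8052,0.6970
Breast,IRF,SKPCA,eq36,6,0.8984,0.8050,0.8165,0.8060
Breast,IRF,WKPCA,eq33,6,0.8979,0.7828,0.8990,0.8125
DLBCL-B,NB,AV,,661,0.9444,0.9342,0.9395,0.9327
DLBCL-B,NB,PCA,,8,0.8444,0.8356,0.8337,0.8297
DLBCL-B,NB,SKPCA,eq36,8,0.4111,0.3469,0.3849,0.3726
DLBCL-B,NB,WKPCA,eq33,8,0.9333,0.9220,0.9303,0.9243
DLBCL-B,SVM,AV,,661,0.4833,0.3333,0.3786,0.3460
DLBCL-B,SVM,PCA,,4,0.9611,0.9543,0.9563,0.9543
DLBCL-B,SVM,SKPCA,eq36,4,0.5000,0.3592,0.3862,0.3640
DLBCL-B,SVM,WKPCA,eq33,4,0.9556,0.9561,0.9485,0.9507
DLBCL-B,KNN,AV,,661,0.8500,0.8168,0.8610,0.8189
DLBCL-B,KNN,PCA,,5,0.9556,0.9498,0.9481,0.9480
DLBCL-B,KNN,SKPCA,eq36,5,0.7611,0.7400,0.7412,0.7201
DLBCL-B,KNN,WKPCA,eq33,5,0.9444,0.9377,0.9368,0.9358
DLBCL-B,RF,AV,,661,0.3833,0.9080,0.9290,0.9143
DLBCL-B,RF,PCA,,6,0.9167,0.8989,0.9162,0.9008
DLBCL-B,RF,SKPCA,eq36,6,0.7667,0.7086,0.7302,0.7011
DLBCL-B,RF,WKPCA,eq34,6,0.9500,0.9447,0.9425,0.9397
DLBCL-B,IRF,AV,,661,0.8944,0.8717,0.8918,0.8780
DLBCL-B,IRF,PCA,,5,0.9167,0.9024,0.9121,0.9004
DLBCL-B,IRF,SKPCA,eq36,5,0.7778,0.7331,0.7432,0.7262
DLBCL-B,IRF,WKPCA,eq33,5,0.9722,0.8877,0.8838,0.8806
DLBCL-D,NB,AV,,3795,NA,NA,NA,NA
DLBCL-D,NB,PCA,,9,0.6828,0.7033,0.6881,0.6646
DLBCL-D,NB,SKPCA,eq36,9,0.2791,0.3548,0.3933,0.3660
DLBCL-D,NB,WKPCA,eq34,9,0.7683,0.7811,0.7543,0.7529
DLBCL-D,SVM,AV,,3795,0.3803,0.2500,0.3021,0.3720
DLBCL-D,SVM,PCA,,9,0.7142,0.6932,0.7500,0.6833
DLBCL-D,SVM,SKPCA,eq36,9,0.4191,0.3285,0.3570,0.3430
DLBCL-D,SVM,WKPCA,eq34,9,0.8071,0.7978,0.8251,0.7859
DLBCL-D,KNN,AV,,3795,0.6822,0.6119,0.7135,0.6131
DLBCL-D,KNN,PCA,,10,0.6514,0.6052,0.6533,0.6042
DLBCL-D,KNN,SKPCA,eq36,10,0.2954,0.2476,0.2667,0.2665
DLBCL-D,KNN,WKPCA,eq33,10,0.7054,0.6664,0.6989,0.6674
DLBCL-D,RF,AV,,3795,0.7364,0.6516,0.7204,0.6670
DLBCL-D,RF,PCA,,17,0.7287,0.6641,0.7183,0.6627
DLBCL-D,RF,SKPCA,eq36,17,0.5504,0.4872,0.5815,0.4862
DLBCL-D,RF,WKPCA,eq34,17,0.7442,0.7004,0.7579,0.7062
DLBCL-D,IRF,AV,,3795,0.7683,0.7359,0.7694,0.7271
DLBCL-D,IRF,PCA,,9,0.6840,0.6685,0.7080,0.6600
DLBCL-D,IRF,SKPCA,eq36,9,0.4585,0.3678,0.3968,0.3864
DLBCL-D,IRF,WKPCA,eq33,9,0.7286,0.6978,0.6986,0.6812
Leukaemia,NB,AV,,985,0.9758,0.9458,0.9537,0.9476
Leukaemia,NB,PCA,,7,0.9799,0.9637,0.9712,0.9616
Leukaemia,NB,SKPCA,eq36,7,0.3993,0.2675,0.3070,0.2840
Leukaemia,NB,WKPCA,eq33,7,0.9677,0.9372,0.9646,0.9440
Leukaemia,SVM,AV,,985,0.3188,0.1667,0.1826,0.1750
Leukaemia,SVM,PCA,,11,0.9838,0.9597,0.9866,0.9682
Leukaemia,SVM,SKPCA,eq36,11,0.8509,0.7158,0.7540,0.7225
Leukaemia,SVM,WKPCA,eq35,11,0.9758,0.9215,0.9540,0.9350
Leukaemia,KNN,AV,,985,0.9477,0.9000,0.9048,0.8779
Leukaemia,KNN,PCA,,9,0.9759,0.9519,0.9467,0.9480
Leukaemia,KNN,SKPCA,eq36,9,0.7903,0.6487,0.6850,0.6560
Leukaemia,KNN,WKPCA,eq33,9,0.9838,0.9597,0.9813,0.9652
Leukaemia,RF,AV,,985,0.9718,0.9250,0.9450,0.9359
Leukaemia,RF,PCA,,19,0.9878,0.9722,0.9837,0.9729
Leukaemia,RF,SKPCA,eq36,19,0.2943,0.1667,0.2040,0.1890
Leukaemia,RF,WKPCA,eq35,19,0.9637,0.9120,0.9850,0.9720
Leukaemia,IRF,AV,,985,0.9516,0.9130,0.9197,0.9138
Leukaemia,IRF,PCA,,26,0.7683,0.9469,0.9814,0.9633
Leukaemia,IRF,SKPCA,eq36,26,0.8344,0.7579,0.8075,0.7889
Leukaemia,IRF,WKPCA,eq35,26,0.9717,0.9510,0.9565,0.9466
Multi-A,NB,AV,,5565,NA,NA,NA,NA
Multi-A,NB,PCA,,10,0.9214,0.9324,0.9303,0.9206
Multi-A,NB,SKPCA,eq36,10,0.4743,0.4508,0.4825,0.4670
Multi-A,NB,WKPCA,eq35,10,0.9224,0.9229,0.9305,0.9227
Multi-A,SVM,AV,,5565,0.1933,0.2655,0.3045,0.2880
Multi-A,SVM,PCA,,14,0.9800,0.9875,0.9800,0.9804
Multi-A,SVM,SKPCA,eq36,14,0.3105,0.3942,0.4120,0.4050
Multi-A,SVM,WKPCA,eq35,14,0.9805,0.9838,0.9775,0.9784
Multi-A,KNN,AV,,5565,0.9519,0.9557,0.9442,0.9455
Multi-A,KNN,PCA,,9,0.9510,0.9546,0.9529,0.9454
Multi-A,KNN,SKPCA,eq36,9,0.1743,0.2500,0.2656,0.2765
Multi-A,KNN,WKPCA,eq33,9,0.9705,0.9775,0.9700,0.9692
Multi-A,RF,AV,,5565,0.9705,0.9775,0.9700,0.9692
Multi-A,RF,PCA,,29,0.9800,0.9875,0.9800,0.9804
Multi-A,RF,SKPCA,eq36,29,0.7948,0.8039,0.7952,0.7789
Multi-A,RF,WKPCA,eq33,29,0.9805,0.9882,0.9750,0.9794
Multi-A,IRF,AV,,5565,0.9705,0.9754,0.9700,0.9685
Multi-A,IRF,PCA,,17,0.9414,0.9408,0.9538,0.9379
Multi-A,IRF,SKPCA,eq36,17,0.7648,0.7734,0.7728,0.7490
Multi-A,IRF,WKPCA,eq35,17,0.9419,0.9497,0.9388,0.9392
Lung,NB,AV,,1001,0.9645,0.9668,0.9454,0.9518
Lung,NB,PCA,,4,0.9645,0.9519,0.9616,0.9526
Lung,NB,SKPCA,eq36,4,0.7922,0.8049,0.7429,0.7527
Lung,NB,WKPCA,eq35,4,0.9696,0.9623,0.9635,0.9590
Lung,SVM,AV,,1001,0.7055,0.2500,0.2890,0.2660
Lung,SVM,PCA,,8,0.9746,0.9703,0.9693,0.9675
Lung,SVM,SKPCA,eq36,8,0.7208,0.3168,0.3430,0.3245
Lung,SVM,WKPCA,eq35,8,0.9796,0.9721,0.9767,0.9628
Lung,KNN,AV,,1001,0.9392,0.8849,0.9394,0.9056
Lung,KNN,PCA,,7,0.9644,0.9417,0.9644,0.9502
Lung,KNN,SKPCA,eq36,7,0.8779,0.8204,0.8150,0.7988
Lung,KNN,WKPCA,eq33,7,0.9695,0.9536,0.9677,0.9574
Lung,RF,AV,,1001,0.9542,0.8997,0.9670,0.9201
Lung,RF,PCA,,7,0.9594,0.9400,0.9583,0.9453
Lung,RF,SKPCA,eq36,7,0.8374,0.6857,0.6717,0.6467
Lung,RF,WKPCA,eq33,7,0.9645,0.9519,0.9616,0.9526
Lung,IRF,AV,,1001,0.9390,0.8882,0.9400,0.9102
Lung,IRF,PCA,,10,0.9593,0.9399,0.9554,0.9444
Lung,IRF,SKPCA,eq36,10,0.9389,0.8756,0.9411,0.8965
Lung,IRF,WKPCA,eq33,10,0.9645,0.9519,0.9616,0.9526
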
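dataset,model,metric,value
Elderly,RF,Accuracy,0.699
Elderly,RF,Precision,0.671
Elderly,RF,AUC,0.645
Elderly,SVM,Accuracy,0.712
Elderly,SVM,Precision,0.661
Elderly,SVM,AUC,0.650
Elderly,LR,Accuracy,0.698
Elderly,LR,Precision,0.647
Elderly,LR,AUC,0.634
LLOS,RF,Accuracy,0.858
LLOS,RF,Precision,0.927
LLOS,RF,AUC,0.855
LLOS,SVM,Accuracy,0.869
LLOS,SVM,Precision,0.908
LLOS,SVM,AUC,0.855
LLOS,LR,Accuracy,0.884
LLOS,LR,Precision,0.935
LLOS,LR,AUC,0.866
Stroke,RF,Accuracy,0.805
Stroke,RF,Precision,0.730
Stroke,RF,AUC,0.703
Stroke,SVM,Accuracy,0.829
Stroke,SVM,Precision,0.735
Stroke,SVM,AUC,0.716
Stroke,LR,Accuracy,0.800
Stroke,LR,Precision,0.625
Stroke,LR,AUC,0.666
ARF,RF,Accuracy,0.630
ARF,RF,Precision,0.646
ARF,RF,AUC,0.619
ARF,SVM,Accuracy,0.559
ARF,SVM,Precision,0.622
ARF,SVM,AUC,0.547
ARF,LR,Accuracy,0.606
ARF,LR,Precision,0.694
ARF,LR,AUC,0.596
CIR,RF,Accuracy,0.767
CIR,RF,Precision,0.800
CIR,RF,AUC,0.737
CIR,SVM,Accuracy,0.837
CIR,SVM,Precision,0.688
CIR,SVM,AUC,0.737
CIR,LR,Accuracy,0.767
CIR,LR,Precision,0.733
CIR,LR,AUC,0.670
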
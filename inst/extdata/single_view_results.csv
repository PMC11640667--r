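model,backbone,view,top1,top5,mean_precision,mean_recall,mean_f1
MobileNetV3-L,MobileNetV3,L,98.15,99.35,98.22,98.15,98.13
MobileNetV3-F,MobileNetV3,F,98.8,99.72,98.86,98.8,98.8
MobileNetV3-R,MobileNetV3,R,97.87,99.44,98,97.87,97.87
MobileNetV3-B,MobileNetV3,B,99.07,99.91,99.12,99.07,99.08
MobileNetV3-S,MobileNetV3,S,99.54,100,99.56,99.54,99.54
MobileViT-L,MobileViT,L,98.52,99.44,98.59,98.52,98.52
MobileViT-F,MobileViT,F,98.98,99.72,99.02,98.98,98.98
MobileViT-R,MobileViT,R,98.24,99.54,98.33,98.24,98.24
MobileViT-B,MobileViT,B,99.26,99.91,99.3,99.26,99.26
MobileViT-S,MobileViT,S,99.63,100,99.66,99.63,99.63
ResNet18-L,ResNet18,L,94.91,98.06,95.13,94.91,94.89
ResNet18-F,ResNet18,F,96.48,99.07,96.61,96.48,96.46
ResNet18-R,ResNet18,R,95.28,98.89,95.49,95.28,95.28
ResNet18-B,ResNet18,B,96.67,99.17,96.77,96.67,96.67
ResNet18-S,ResNet18,S,98.7,99.91,98.77,98.7,98.7
VGG16-L,VGG16,L,93.89,97.78,94.14,93.89,93.91
VGG16-F,VGG16,F,95.93,98.43,96.07,95.93,95.93
VGG16-R,VGG16,R,94.26,97.59,94.5,94.26,94.28
VGG16-B,VGG16,B,96.67,99.07,96.78,96.67,96.66
VGG16-S,VGG16,S,98.52,99.91,98.59,98.52,98.51
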
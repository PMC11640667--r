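model,backbone,combination,top1,top5,mean_precision,mean_recall,mean_f1
MobileNetV3-S-F,MobileNetV3,S-F,100,100,100,100,100
MobileNetV3-S-R,MobileNetV3,S-R,99.91,100,99.91,99.91,99.91
MobileNetV3-S-L,MobileNetV3,S-L,99.91,100,99.91,99.91,99.91
MobileNetV3-S-B,MobileNetV3,S-B,100,100,100,100,100
MobileNetV3-F-R,MobileNetV3,F-R,100,100,100,100,100
MobileNetV3-F-L,MobileNetV3,F-L,99.91,99.91,99.91,99.91,99.91
MobileNetV3-F-B,MobileNetV3,F-B,100,100,100,100,100
MobileNetV3-L-R,MobileNetV3,L-R,99.91,100,99.91,99.91,99.91
MobileNetV3-R-B,MobileNetV3,R-B,99.72,100,99.74,99.72,99.72
MobileNetV3-L-B,MobileNetV3,L-B,99.91,100,99.91,99.91,99.91
MobileViT-S-F,MobileViT,S-F,100,100,100,100,100
MobileViT-S-R,MobileViT,S-R,99.91,100,99.91,99.91,99.91
MobileViT-S-L,MobileViT,S-L,100,100,100,100,100
MobileViT-S-B,MobileViT,S-B,100,100,100,100,100
MobileViT-F-R,MobileViT,F-R,99.91,100,99.91,99.91,99.91
MobileViT-F-L,MobileViT,F-L,99.91,100,99.91,99.91,99.91
MobileViT-F-B,MobileViT,F-B,100,100,100,100,100
MobileViT-L-R,MobileViT,L-R,100,100,100,100,100
MobileViT-R-B,MobileViT,R-B,100,100,100,100,100
MobileViT-L-B,MobileViT,L-B,100,100,100,100,100
ResNet18-S-F,ResNet18,S-F,99.91,100,99.91,99.91,99.91
ResNet18-S-R,ResNet18,S-R,99.91,100,99.91,99.91,99.91
ResNet18-S-L,ResNet18,S-L,99.91,99.91,99.91,99.91,99.91
ResNet18-S-B,ResNet18,S-B,99.91,100,99.91,99.91,99.91
ResNet18-F-R,ResNet18,F-R,99.72,99.91,99.74,99.72,99.72
ResNet18-F-L,ResNet18,F-L,99.81,99.91,99.82,99.81,99.81
ResNet18-F-B,ResNet18,F-B,99.72,100,99.73,99.72,99.72
ResNet18-L-R,ResNet18,L-R,99.72,100,99.74,99.72,99.72
ResNet18-R-B,ResNet18,R-B,99.81,100,99.82,99.81,99.81
ResNet18-L-B,ResNet18,L-B,99.54,100,99.56,99.54,99.54
VGG16-S-F,VGG16,S-F,99.72,100,99.74,99.72,99.72
VGG16-S-R,VGG16,S-R,99.72,100,99.74,99.72,99.72
VGG16-S-L,VGG16,S-L,99.81,100,99.82,99.81,99.81
VGG16-S-B,VGG16,S-B,99.91,100,99.91,99.91,99.91
VGG16-F-R,VGG16,F-R,99.63,100,99.66,99.63,99.63
VGG16-F-L,VGG16,F-L,99.54,99.91,99.56,99.54,99.53
VGG16-F-B,VGG16,F-B,99.72,100,99.74,99.72,99.72
VGG16-L-R,VGG16,L-R,99.35,100,99.38,99.35,99.35
VGG16-R-B,VGG16,R-B,99.44,99.72,99.47,99.44,99.44
VGG16-L-B,VGG16,L-B,99.63,100,99.65,99.63,99.63
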
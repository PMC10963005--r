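frame,bodypart,x_mm,y_mm,likelihood
0,fHead,1.5,-2.7,1
0,fPro,1.7,-4.0,1
0,fTip,2.1,-8.55,1
0,mHead,0,2.2,1
0,mPro,0,1.1,1
0,mTip,0,-2.75,1
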
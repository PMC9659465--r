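class,response,intercept,ame,amen,cp,ee,cf,adf,ndf,st,r2
wheat,ne,-14.227,1.968,,,,,-0.411,,,0.999
wheat_bran,ne,20.870,,,-0.362,,-0.382,-0.244,,,0.785
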
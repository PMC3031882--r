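case,chrom,start,end,type,status,wk0,wk2,wk5
CE01-02,1,108.1,119.9,Loss,Het,2;3,1;3;4,
CE01-02,1,CEN,QTEL,Gain,Het,2;3,1;2;3;4,
CE01-02,3,55.8,CEN,Loss,Het,2;3,1;2;3;4,
CE01-02,3,153.8,QTEL,Gain,Hom,,,
CE01-02,4,86.6,QTEL,Loss,Het,2;3;4,,
CE01-02,11,74.7,85.3,Gain,Het,3;4,,
CE01-02,11,85.3,QTEL,Loss,Het,4,,
CE01-02,11,94.8,QTEL,Loss,Het,2;3,1;2;3;4,
CE01-02,17,28.5,29.7,Amplicon,Het,2;3;4,,
CE01-02,17,34.9,35.3,Amplicon,Het,2;3;4,,
CE01-02,17,43.9,QTEL,Gain,Het,4,,
CE01-02,17,47.0,QTEL,Gain,Het,,4,
CE01-02,17,PTEL,QTEL,Gain,Het,2;3,1,
CE01-02,19,PTEL,14.5,Gain,Het,,1;2,
CE01-02,19,9.5,14.5,Gain,Het,3;4,,
CE01-02,19,PTEL,QTEL,Loss,Het,,3;4,
CE01-02,X,PTEL,QTEL,Gain,Het,2;3,1,
CE01-13,3,141.6,QTEL,Gain,Hom,,,
CE01-13,4,167.4,170.1,Loss,Hom,,,
CE01-13,9,PTEL,13.2,Loss,Hom,,,
CE01-13,10,PTEL,QTEL,Gain,Het,1;2,,
CE01-13,15,25.0,80.7,Loss,Het,3,,2
CE01-13,15,25.0,45.7,Loss,Het,1;2;4,,
CE01-13,15,45.7,46.2,Gain,Het,1;2;4,,
CE01-13,15,46.2,60.7,Loss,Het,1;2;4,,
CE01-13,15,60.7,77.7,Gain,Het,1;2,,
CE01-13,15,60.7,61.7,Gain,Het,4,,
CE01-13,15,75.9,77.7,Gain,Het,4,,
CE01-13,15,77.7,77.9,Loss,Het,1;2;4,,
CE01-13,15,77.9,78.1,Gain,Het,1;2;4,,
CE01-13,15,78.1,81.0,Loss,Het,1;2;4,,
CE01-13,15,81.0,89.3,Gain,Het,1;2;4,,
CE01-13,15,89.3,QTEL,Loss,Hom,,,
CE01-13,16,CEN,QTEL,Loss,Het,3;4,,2
CE01-13,18,23.2,QTEL,Loss,Het,3;4,,2
CE01-13,19,PTEL,CEN,Gain,Het,1;2,,
CE01-13,19,CEN,51.5,Further gain,Het,1;2,,
CE01-13,19,CEN,QTEL,Gain,Het,3;4,,2
CE01-13,20,20.5,22.1,Loss,Het,3;4,,2
CE01-13,X,65.0,QTEL,Loss,Het,3;4,,2
CE01-09,2,PTEL,180.6,Gain,Het,3,,
CE01-09,5,PTEL,5.1,Gain,Het,3,,
CE01-09,5,5.1,CEN,Further gain,Het,3,,
CE01-09,5,CEN,QTEL,Loss,Het,3,,
CE01-09,6,PTEL,35.6,Gain,Het,3,,
CE01-09,7,PTEL,2.3,Gain,Het,3,,
CE01-09,7,2.3,CEN,Loss,Het,3,,
CE01-09,8,PTEL,QTEL,Gain,Het,3,,
CE01-09,10,PTEL,27.8,Loss,Het,3,,
CE01-09,10,87.3,QTEL,Loss,Het,3,,
CE01-09,11,75.1,98.9,Gain,Hom,,,
CE01-09,11,98.9,104.4,Further gain,Hom,,,
CE01-09,11,104.4,QTEL,Loss,Hom,,,
CE01-09,16,PTEL,CEN,Loss,Het,3,,
CE01-09,16,80.3,QTEL,Gain,Het,3,,
CE01-09,18,PTEL,QTEL,Loss,Het,3,,
CE01-09,19,PTEL,CEN,Loss,Het,3,,
CE01-09,19,PTEL,QTEL,Loss,Het,1,,1
CE01-09,21,PTEL,33.5,Loss,Het,3,,
CE01-09,22,PTEL,QTEL,Loss,Het,3,,
CE01-09,X,PTEL,QTEL,Gain,Het,3,,
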
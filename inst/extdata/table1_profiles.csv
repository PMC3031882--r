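case,quadrant,week,abnormal,tumour_pct
CE01-01,1,0,F,0
CE01-01,2,0,F,
CE01-01,3,0,F,0
CE01-01,4,0,T,
CE01-01,1,2,F,
CE01-01,2,2,F,
CE01-01,3,2,,
CE01-01,4,2,F,
CE01-01,1,5,F,
CE01-01,2,5,F,
CE01-01,3,5,F,1
CE01-01,4,5,F,<1
CE01-02,1,0,,
CE01-02,2,0,T,
CE01-02,3,0,T,85
CE01-02,4,0,T,
CE01-02,1,2,T,
CE01-02,2,2,T,10
CE01-02,3,2,T,40
CE01-02,4,2,T,
CE01-02,1,5,F,
CE01-02,2,5,F,
CE01-02,3,5,F,
CE01-02,4,5,,
CE01-03,1,0,,
CE01-03,2,0,F,10
CE01-03,3,0,F,0
CE01-03,4,0,F,30
CE01-03,1,2,,
CE01-03,2,2,F,
CE01-03,3,2,F,
CE01-03,4,2,F,
CE01-03,1,5,,
CE01-03,2,5,F,0
CE01-03,3,5,F,
CE01-03,4,5,F,<1
CE01-04,1,0,F,
CE01-04,2,0,F,
CE01-04,3,0,F,50
CE01-04,4,0,F,
CE01-04,1,2,,
CE01-04,2,2,F,
CE01-04,3,2,F,
CE01-04,4,2,F,
CE01-04,1,5,F,
CE01-04,2,5,F,0
CE01-04,3,5,F,
CE01-04,4,5,F,
CE01-06,1,0,F,
CE01-06,2,0,,
CE01-06,3,0,T,
CE01-06,4,0,F,
CE01-06,1,2,,
CE01-06,2,2,,
CE01-06,3,2,,
CE01-06,4,2,,
CE01-06,1,5,F,
CE01-06,2,5,,
CE01-06,3,5,F,
CE01-06,4,5,F,0
CE01-09,1,0,T,
CE01-09,2,0,,
CE01-09,3,0,T,
CE01-09,4,0,,
CE01-09,1,2,,
CE01-09,2,2,,
CE01-09,3,2,,
CE01-09,4,2,,
CE01-09,1,5,T,8
CE01-09,2,5,,
CE01-09,3,5,,
CE01-09,4,5,,
CE01-10,1,0,F,10
CE01-10,2,0,,
CE01-10,3,0,,
CE01-10,4,0,F,5
CE01-10,1,2,,
CE01-10,2,2,,
CE01-10,3,2,,
CE01-10,4,2,,
CE01-10,1,5,F,
CE01-10,2,5,,
CE01-10,3,5,,
CE01-10,4,5,F,
CE01-12,1,0,F,40
CE01-12,2,0,,
CE01-12,3,0,,
CE01-12,4,0,F,20
CE01-12,1,2,,
CE01-12,2,2,,
CE01-12,3,2,,
CE01-12,4,2,,
CE01-12,1,5,F,
CE01-12,2,5,,
CE01-12,3,5,,
CE01-12,4,5,F,5
CE01-13,1,0,T,40
CE01-13,2,0,T,
CE01-13,3,0,T,
CE01-13,4,0,T,
CE01-13,1,2,,
CE01-13,2,2,,
CE01-13,3,2,,
CE01-13,4,2,,
CE01-13,1,5,F,
CE01-13,2,5,T,
CE01-13,3,5,,
CE01-13,4,5,F,3
CE01-14,1,0,T,70
CE01-14,2,0,,
CE01-14,3,0,T,
CE01-14,4,0,,
CE01-14,1,2,,
CE01-14,2,2,,
CE01-14,3,2,,
CE01-14,4,2,,
CE01-14,1,5,F,
CE01-14,2,5,,
CE01-14,3,5,F,
CE01-14,4,5,,
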
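"age","bmi","smoker","exercise","proc_meat","poultry","fish","legumes","death"
79,28.1,0,3.6,2,6,1,2,0
68,28.4,0,3.7,1,0,1,2,0
62,25.7,0,2.3,1,3,2,5,0
61,21.3,0,8.3,0,2,2,0,0
65,27.2,0,0.6,5,2,1,0,0
75,19.6,0,1.4,0,1,4,4,0
66,30,0,1.7,5,2,1,3,0
78,30.1,0,11,1,1,0,3,0
63,29.4,0,1.3,0,4,1,3,0
69,26.5,1,2.5,2,3,1,2,0
63,24.3,0,1,1,3,1,1,1
64,27.8,0,3.7,1,1,2,4,1
75,28.6,1,6.8,1,2,4,2,0
62,28.4,1,3.6,1,0,0,1,0
69,22.4,0,3.9,0,4,5,2,0
62,32.2,0,3.3,0,4,1,4,1
71,21,0,11.4,5,2,1,2,0
60,30.4,0,2.9,3,3,1,1,0
79,29.9,0,0.4,1,1,0,2,0
66,27.2,0,1.6,1,3,0,2,0
72,19.8,0,0.3,3,0,1,1,1
66,32.3,0,4,0,3,1,0,0
79,28.8,1,1.3,1,1,1,2,1
77,25.3,0,8,4,2,1,1,0
79,28.9,1,5.2,3,1,2,2,0
61,32.1,0,0.4,3,1,0,1,0
72,28,0,0.7,3,1,0,1,0
69,26.1,0,4.3,1,2,1,1,0
78,20.1,0,2.5,6,4,2,1,0
67,30.1,0,3.7,3,2,1,1,0
73,23.6,1,8.4,2,2,3,2,0
65,29.2,0,0.5,1,2,1,1,0
64,29.5,0,1.5,0,5,1,3,0
64,27.5,0,3.2,1,1,2,3,0
67,30.5,0,2.1,2,4,2,3,0
76,23,0,1.5,2,5,0,4,0
69,27.8,0,5.9,3,3,3,3,0
75,29.7,0,0.2,5,2,0,1,0
76,27.1,0,1.3,2,1,1,2,0
69,30,1,6.7,0,0,1,0,0
75,20.2,0,3.3,1,2,0,0,1
67,22.5,0,1.2,3,2,0,3,0
74,26.7,0,1.6,3,2,1,2,0
68,26.8,1,3.4,1,2,0,2,0
77,27.9,1,2.2,0,2,1,3,0
66,25.7,0,3.4,3,4,0,1,1
62,22.4,0,3.5,6,2,1,4,0
76,27.9,0,1.7,5,4,1,4,0
77,27.4,0,2.2,1,4,1,0,0
78,21.6,0,1.5,2,1,4,0,0
71,24.6,0,6.3,1,3,4,3,0
74,30.4,1,5,1,1,0,4,0
75,22.4,0,0.1,0,3,3,4,1
72,25.2,0,3.1,3,1,0,4,1
74,28.7,0,1.4,0,6,2,3,1
67,22.8,0,0.2,2,1,1,1,1
63,19.6,0,4,2,0,4,2,0
64,30.7,0,2,3,0,0,2,1
67,30.9,0,1.4,1,1,1,3,0
65,26,0,1.8,3,2,1,1,0
64,27.4,0,6.5,1,2,2,1,0
70,26.4,0,5.8,2,1,0,1,0
75,26,0,4.7,3,1,4,0,0
73,29,0,3.8,0,3,4,3,0
70,30.2,0,10,0,0,2,0,0
73,24.7,1,2.8,4,1,1,0,0
69,27.3,0,0.2,1,4,1,0,0
69,28.7,0,0.5,6,1,1,0,0
66,27.3,0,3.9,0,3,0,1,0
68,18.3,0,1.9,3,1,0,1,0
65,16.6,0,0.4,0,0,0,0,0
71,27.9,1,12,0,1,0,3,0
76,30.7,0,4.2,2,1,1,3,0
72,20.8,0,0.8,1,3,0,0,0
63,28.5,0,5.7,2,4,1,0,0
71,27,0,0.3,3,4,2,2,0
68,28.9,0,3.5,0,0,1,3,0
68,31.3,0,1.6,2,2,2,3,1
72,26.6,0,2.9,0,0,2,1,0
78,23.6,0,0.7,0,5,0,3,0
77,34.8,0,0.4,0,2,3,2,0
77,35.3,0,1.7,1,3,3,4,0
65,30.5,0,0.5,0,0,3,1,0
74,25.2,1,2.2,1,4,1,1,0
67,27.9,0,2.3,3,3,1,2,0
62,23.8,0,1.9,1,2,0,2,0
62,30.2,0,2.7,2,1,3,1,0
74,27.7,0,5.8,3,2,2,3,0
67,18.7,0,3.9,2,8,2,2,1
68,23.2,0,0.7,2,2,1,2,0
67,18.3,0,0.3,1,0,3,1,0
60,30.8,0,2.2,3,3,4,3,0
77,24.9,1,2.5,3,1,3,5,0
63,21.6,0,0.3,1,2,1,4,0
74,25.6,0,1,1,2,3,1,0
71,27.4,0,0.8,1,1,2,2,0
70,22.5,0,0,0,3,1,2,0
67,25.8,0,0.1,3,4,1,3,0
76,23.7,0,2.3,2,3,0,1,0
64,28.6,0,5.2,1,3,3,2,0
68,34.1,0,0.8,3,1,2,4,0
69,29.4,0,0.4,2,0,2,2,0
69,25.9,0,5.9,1,2,1,4,0
67,28.4,0,3.8,3,2,1,3,0
72,30.9,0,7.6,1,2,1,1,0
67,21.3,0,1.8,0,0,3,2,0
78,23.6,0,8,2,5,1,3,0
61,27.5,0,9.5,2,1,2,3,0
75,20.4,0,0.6,2,2,1,5,0
64,30.9,1,6.4,1,3,0,4,0
73,26.1,0,3.8,2,5,2,2,0
68,19.5,0,1,3,2,3,1,0
61,23.3,0,0.7,0,3,1,3,0
74,23.7,0,0.2,3,2,2,1,0
72,22.4,0,0.1,5,4,1,0,0
72,32,0,1.7,2,3,4,1,0
71,25.5,0,0.7,2,1,2,0,0
75,26.4,0,4.1,1,1,2,2,0
63,21.9,1,1.9,5,2,2,5,0
76,24.2,0,2.4,1,1,1,0,0
70,25.2,0,0.5,1,2,2,0,0
69,20.9,1,5.8,4,1,1,3,0
71,29.8,0,4.2,1,1,5,0,0
64,27.9,0,2.5,4,2,3,2,0
73,23.8,0,2.5,5,1,0,7,0
66,31,0,2.3,2,1,1,1,0
74,25.9,0,8.6,3,5,2,3,0
63,22.8,0,2.2,3,1,1,1,0
72,24.4,0,3.2,0,0,0,3,0
62,18.4,0,4.5,2,2,1,1,0
76,29.9,0,0.5,2,4,2,3,0
75,23.9,0,1.3,3,2,2,2,1
75,26.1,0,3.5,2,0,2,1,0
70,25,0,4.5,2,6,2,1,0
77,32.1,0,6.6,1,1,0,2,1
72,20.1,0,3.9,2,1,2,0,0
77,25.9,1,7.8,2,3,2,4,0
75,26.1,0,1.3,2,0,3,5,0
74,26,0,4.2,4,1,2,1,0
75,24.3,0,0.5,7,1,1,1,0
73,24.4,0,1.8,2,1,2,3,0
70,26.6,0,3.3,2,1,2,1,0
63,22.1,0,2.6,0,2,0,0,0
71,32.2,0,1.7,2,0,1,3,0
65,24.5,0,8.5,1,0,2,3,0
74,33.8,0,0.5,0,1,2,3,0
64,23.6,0,0.7,0,0,2,1,0
78,25.7,0,0,3,1,0,3,0
61,18.7,0,1.6,0,0,0,1,0
78,29.2,0,4.6,1,2,6,2,0
62,20.1,0,0.3,1,0,1,2,0
77,14.1,0,4.7,0,4,1,3,0
64,20.6,0,6,3,1,2,1,0
64,24.9,1,0.8,6,2,1,5,0
65,24.5,0,1.1,2,2,0,4,1
75,23.6,0,0.2,0,4,1,1,0
69,23.4,0,2.4,3,2,1,2,0
75,33,1,2.4,2,0,3,5,1
79,25.9,0,1.8,3,3,0,0,0
75,26.6,0,8.2,0,3,0,1,0
72,23,0,5.7,0,0,0,1,0
76,19.8,1,4.2,2,0,1,2,0
70,37,1,3,4,2,3,0,0
73,30.2,0,2.7,1,3,2,3,0
70,29.7,0,1.6,0,0,2,1,0
70,27.9,1,0.7,1,1,1,1,0
67,23.5,0,2,1,1,5,2,0
75,26.2,0,2.6,0,2,2,2,0
64,22.4,0,0.3,2,0,0,1,0
68,31.4,0,3.7,2,0,4,1,0
67,29.2,0,0.1,2,1,1,1,0
75,27.3,0,6.8,2,1,1,0,1
67,25.2,0,0.6,5,3,1,0,0
74,21.7,0,5,5,1,2,1,0
67,26.6,0,1.7,3,0,3,0,0
74,35.9,0,0,4,1,4,4,1
61,29.7,0,2.1,1,6,1,2,0
69,29,0,2.6,2,3,0,2,0
74,31.7,0,1.2,0,3,4,0,0
79,31,0,2.4,2,5,2,2,0
78,34.4,0,3.5,1,1,2,4,1
66,28.8,0,0.7,1,3,1,0,0
65,20.1,0,3.1,2,1,1,3,0
78,23.6,0,4.1,0,1,1,0,0
74,26.6,0,0.5,2,5,0,2,0
74,24,0,1.7,1,4,0,0,0
71,26.6,0,1,2,2,0,0,0
62,27.8,1,0.1,3,3,1,1,0
75,25.4,0,0.1,2,3,1,0,0
65,29.9,0,10.1,3,2,1,1,0
65,23.3,0,2.8,2,2,3,5,0
74,32.6,0,5.6,0,0,3,1,0
76,21.7,0,0.2,3,2,0,3,0
73,26,0,2.3,0,3,1,2,0
61,18.5,0,5.6,0,1,2,2,0
68,26.1,0,4.1,4,0,0,1,0
66,25,0,2.3,2,0,0,0,0
77,22.3,0,1.1,1,0,1,0,0
68,17.3,0,5.1,1,2,1,4,0
67,23.4,0,0.1,1,3,0,1,0
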
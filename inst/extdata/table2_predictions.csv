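subject,sample,actual,nn_m1,nn_m2,nn_m3,knn,sdt,cdt,l_svm,q_svm,c_svm
1,1,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
1,2,lie,truth,lie,lie,truth,truth,truth,truth,lie,truth
1,3,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
2,1,lie,truth,truth,truth,truth,truth,lie,truth,truth,truth
2,2,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
2,3,lie,lie,truth,lie,truth,lie,truth,truth,truth,truth
3,1,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
3,2,lie,lie,truth,lie,lie,truth,lie,lie,lie,lie
3,3,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
4,1,lie,lie,lie,lie,lie,lie,lie,lie,lie,lie
4,2,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
4,3,lie,truth,truth,truth,truth,truth,truth,lie,truth,truth
5,1,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
5,2,lie,lie,truth,lie,truth,truth,truth,truth,lie,lie
5,3,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
6,1,lie,lie,lie,lie,lie,lie,lie,lie,lie,lie
6,2,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
6,3,lie,truth,truth,truth,truth,truth,truth,truth,truth,truth
7,1,truth,truth,truth,truth,truth,truth,lie,truth,truth,truth
7,2,lie,lie,lie,lie,lie,truth,lie,lie,lie,lie
7,3,truth,truth,truth,truth,lie,truth,lie,lie,lie,lie
8,1,lie,lie,lie,lie,lie,lie,lie,lie,lie,lie
8,2,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
8,3,lie,truth,lie,lie,truth,truth,truth,truth,truth,truth
9,1,truth,truth,truth,truth,truth,truth,truth,truth,truth,truth
9,2,lie,lie,lie,lie,truth,lie,truth,truth,lie,lie
9,3,truth,truth,truth,truth,lie,truth,lie,lie,lie,lie
10,1,lie,lie,lie,lie,lie,lie,lie,lie,lie,lie
10,2,truth,truth,truth,truth,lie,truth,lie,truth,truth,truth
10,3,lie,truth,lie,lie,truth,truth,truth,lie,lie,lie
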
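species,colony,stage,n_tested,n_infected
A,T7,queen,1,1
A,T7,larva,6,5
A,T7,worker,10,7
A,T7,white_soldier,4,2
A,T7,soldier,6,6
A,T16,queen,1,1
A,T16,larva,15,13
A,T16,worker,10,9
A,T16,white_soldier,1,1
A,T16,soldier,10,4
A,T42,queen,1,1
A,T42,king,1,1
A,T42,larva,21,10
A,T42,worker,10,4
A,T42,white_soldier,4,3
A,T42,soldier,20,16
B,T5,queen,1,1
B,T5,king,1,0
B,T5,worker,15,0
B,T5,white_soldier,5,4
B,T5,soldier,3,0
B,T26,queen,1,1
B,T26,worker,9,0
B,T26,white_soldier,4,3
B,T26,soldier,10,1
B,T34,queen,1,1
B,T34,larva,19,13
B,T34,worker,15,12
B,T34,soldier,15,13
B,T37,queen,1,1
B,T37,king,1,1
B,T37,worker,20,0
B,T37,white_soldier,5,1
B,T37,soldier,15,1
B,T38,queen,1,1
B,T38,king,1,1
B,T38,larva,19,4
B,T38,worker,12,3
B,T38,white_soldier,1,1
B,T38,soldier,14,7
C,T17,queen,1,1
C,T17,worker,16,14
C,T17,white_soldier,1,1
C,T17,soldier,1,0
C,T24,queen,1,1
C,T24,king,1,1
C,T24,larva,25,16
C,T24,worker,10,3
C,T24,white_soldier,2,2
C,T24,soldier,10,3
C,T31,larva,10,9
C,T31,worker,9,1
C,T31,white_soldier,30,21
C,T31,soldier,6,1
C,T45,larva,10,7
C,T45,worker,3,0
C,T45,white_soldier,2,2
C,T45,soldier,5,0
C,T46,queen,1,1
C,T46,larva,9,5
C,T46,worker,10,0
C,T46,white_soldier,3,2
C,T46,soldier,10,0
C,TX,queen,1,1
C,TX,king,1,0
C,TX,larva,10,8
C,TX,worker,10,1
C,TX,white_soldier,10,9
C,TX,soldier,10,0
D,TD1,queen,1,1
D,TD1,king,1,1
D,TD1,worker,10,1
D,TD1,white_soldier,5,5
D,TD1,soldier,10,4
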
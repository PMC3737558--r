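"V1","V2","V3"
1,0,0
0.987688340595138,0.156434465040231,0
0.951056516295154,0.309016994374947,0
0.891006524188368,0.453990499739547,0
0.809016994374947,0.587785252292473,0
0.707106781186548,0.707106781186547,0
0.587785252292473,0.809016994374947,0
0.453990499739547,0.891006524188368,0
0.309016994374947,0.951056516295154,0
0.156434465040231,0.987688340595138,0
6.12323399573677e-17,1,0
-0.156434465040231,0.987688340595138,0
-0.309016994374947,0.951056516295154,0
-0.453990499739547,0.891006524188368,0
-0.587785252292473,0.809016994374947,0
-0.707106781186547,0.707106781186548,0
-0.809016994374947,0.587785252292473,0
-0.891006524188368,0.453990499739547,0
-0.951056516295154,0.309016994374948,0
-0.987688340595138,0.156434465040231,0
-1,1.22464679914735e-16,0
-0.987688340595138,-0.156434465040231,0
-0.951056516295154,-0.309016994374947,0
-0.891006524188368,-0.453990499739547,0
-0.809016994374948,-0.587785252292473,0
-0.707106781186548,-0.707106781186547,0
-0.587785252292473,-0.809016994374947,0
-0.453990499739547,-0.891006524188368,0
-0.309016994374948,-0.951056516295154,0
-0.156434465040231,-0.987688340595138,0
-1.83697019872103e-16,-1,0
0.156434465040231,-0.987688340595138,0
0.309016994374947,-0.951056516295154,0
0.453990499739547,-0.891006524188368,0
0.587785252292473,-0.809016994374948,0
0.707106781186547,-0.707106781186548,0
0.809016994374947,-0.587785252292473,0
0.891006524188368,-0.453990499739547,0
0.951056516295154,-0.309016994374948,0
0.987688340595138,-0.156434465040231,0
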
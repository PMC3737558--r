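"V1","V2","V3"
11,0,0
10.9876883405951,0.156434465040231,0
10.9510565162952,0.309016994374947,0
10.8910065241884,0.453990499739547,0
10.8090169943749,0.587785252292473,0
10.7071067811865,0.707106781186547,0
10.5877852522925,0.809016994374947,0
10.4539904997395,0.891006524188368,0
10.3090169943749,0.951056516295154,0
10.1564344650402,0.987688340595138,0
10,1,0
9.84356553495977,0.987688340595138,0
9.69098300562505,0.951056516295154,0
9.54600950026045,0.891006524188368,0
9.41221474770753,0.809016994374947,0
9.29289321881345,0.707106781186548,0
9.19098300562505,0.587785252292473,0
9.10899347581163,0.453990499739547,0
9.04894348370485,0.309016994374948,0
9.01231165940486,0.156434465040231,0
9,1.22464679914735e-16,0
9.01231165940486,-0.156434465040231,0
9.04894348370485,-0.309016994374947,0
9.10899347581163,-0.453990499739547,0
9.19098300562505,-0.587785252292473,0
9.29289321881345,-0.707106781186547,0
9.41221474770753,-0.809016994374947,0
9.54600950026045,-0.891006524188368,0
9.69098300562505,-0.951056516295154,0
9.84356553495977,-0.987688340595138,0
10,-1,0
10.1564344650402,-0.987688340595138,0
10.3090169943749,-0.951056516295154,0
10.4539904997395,-0.891006524188368,0
10.5877852522925,-0.809016994374948,0
10.7071067811865,-0.707106781186548,0
10.8090169943749,-0.587785252292473,0
10.8910065241884,-0.453990499739547,0
10.9510565162952,-0.309016994374948,0
10.9876883405951,-0.156434465040231,0
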
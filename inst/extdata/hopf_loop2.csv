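"V1","V2","V3"
2,0,0
1.98768834059514,0,0.156434465040231
1.95105651629515,0,0.309016994374947
1.89100652418837,0,0.453990499739547
1.80901699437495,0,0.587785252292473
1.70710678118655,0,0.707106781186547
1.58778525229247,0,0.809016994374947
1.45399049973955,0,0.891006524188368
1.30901699437495,0,0.951056516295154
1.15643446504023,0,0.987688340595138
1,0,1
0.843565534959769,0,0.987688340595138
0.690983005625053,0,0.951056516295154
0.546009500260453,0,0.891006524188368
0.412214747707527,0,0.809016994374947
0.292893218813453,0,0.707106781186548
0.190983005625053,0,0.587785252292473
0.108993475811632,0,0.453990499739547
0.0489434837048465,0,0.309016994374948
0.0123116594048623,0,0.156434465040231
0,0,1.22464679914735e-16
0.0123116594048622,0,-0.156434465040231
0.0489434837048464,0,-0.309016994374947
0.108993475811632,0,-0.453990499739547
0.190983005625052,0,-0.587785252292473
0.292893218813452,0,-0.707106781186547
0.412214747707527,0,-0.809016994374947
0.546009500260453,0,-0.891006524188368
0.690983005625052,0,-0.951056516295154
0.843565534959769,0,-0.987688340595138
1,0,-1
1.15643446504023,0,-0.987688340595138
1.30901699437495,0,-0.951056516295154
1.45399049973955,0,-0.891006524188368
1.58778525229247,0,-0.809016994374948
1.70710678118655,0,-0.707106781186548
1.80901699437495,0,-0.587785252292473
1.89100652418837,0,-0.453990499739547
1.95105651629515,0,-0.309016994374948
1.98768834059514,0,-0.156434465040231
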
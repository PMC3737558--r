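"V1","V2","V3"
3,0,0
2.43111698131651,1.62442043319854,0.707106781186547
1.03596491480328,2.50104054746076,1
-0.464838478082599,2.33690083832433,0.707106781186548
-1.41421356237309,1.4142135623731,1.22464679914735e-16
-1.5862402832886,0.315522809981915,-0.707106781186547
-1.19447758258439,-0.494768814657081,-1
-0.597860498879868,-0.894761467893674,-0.707106781186548
-1.83697019872103e-16,-1,-2.44929359829471e-16
0.597860498879867,-0.894761467893674,0.707106781186547
1.19447758258438,-0.494768814657082,1
1.5862402832886,0.315522809981912,0.707106781186548
1.4142135623731,1.41421356237309,3.67394039744206e-16
0.464838478082598,2.33690083832433,-0.707106781186548
-1.03596491480328,2.50104054746076,-1
-2.4311169813165,1.62442043319855,-0.707106781186548
-3,1.10218211923262e-15,-4.89858719658941e-16
-2.43111698131651,-1.62442043319854,0.707106781186548
-1.03596491480328,-2.50104054746076,1
0.464838478082597,-2.33690083832433,0.707106781186549
1.41421356237309,-1.4142135623731,6.12323399573677e-16
1.5862402832886,-0.315522809981914,-0.707106781186548
1.19447758258439,0.494768814657079,-1
0.597860498879868,0.894761467893674,-0.707106781186549
5.51091059616309e-16,1,-7.34788079488412e-16
-0.597860498879867,0.894761467893675,0.707106781186548
-1.19447758258439,0.49476881465708,1
-1.5862402832886,-0.315522809981912,0.707106781186549
-1.41421356237309,-1.4142135623731,8.57252759403147e-16
-0.464838478082603,-2.33690083832433,-0.707106781186548
1.03596491480327,-2.50104054746076,-1
2.4311169813165,-1.62442043319855,-0.707106781186549
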
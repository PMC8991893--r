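channel	Signature.1	Signature.2	Signature.3
A[C>A]A	0.00009600009600010	0.00211500211500211	0.000001
A[C>A]C	0.00151300151300151	0.00000000000000000	0.000004
A[C>A]G	0.00015400015400015	0.00000000000000000	0.000111
A[C>A]T	0.00000000000000000	0.00000000000000000	0.049664
C[C>A]A	0.17727117727117728	0.19190219190219190	0.000168
C[C>A]C	0.00000000000000000	0.00000000000000000	0.000000
C[C>A]G	0.00000000000000000	0.01537201537201537	0.064004
C[C>A]T	0.09101709101709102	0.00000000000000000	0.032411
G[C>A]A	0.00000000000000000	0.00000000000000000	0.003732
G[C>A]C	0.00155500155500155	0.00101500101500102	0.000000
G[C>A]G	0.00000000000000000	0.00000000000000000	0.000000
G[C>A]T	0.00000000000000000	0.00000000000000000	0.000829
T[C>A]A	0.00000000000000000	0.01986901986901987	0.000001
T[C>A]C	0.09633409633409634	0.00000000000000000	0.000043
T[C>A]G	0.00000000000000000	0.00000000000000000	0.497435
T[C>A]T	0.00000000000000000	0.06286206286206286	0.000000
A[C>G]A	0.00000000000000000	0.00005300005300005	0.000000
A[C>G]C	0.00000000000000000	0.00000000000000000	0.000000
A[C>G]G	0.00000000000000000	0.00000000000000000	0.000000
A[C>G]T	0.00028200028200028	0.06943506943506943	0.000000
C[C>G]A	0.00000000000000000	0.00851900851900852	0.000000
C[C>G]C	0.00026900026900027	0.00000000000000000	0.000000
C[C>G]G	0.00000000000000000	0.00000000000000000	0.000000
C[C>G]T	0.01576601576601577	0.00000000000000000	0.002324
G[C>G]A	0.00000000000000000	0.00000000000000000	0.000001
G[C>G]C	0.00000000000000000	0.00000000000000000	0.000000
G[C>G]G	0.00094300094300094	0.00000000000000000	0.000000
G[C>G]T	0.00000000000000000	0.00000000000000000	0.000191
T[C>G]A	0.00000000000000000	0.04031304031304032	0.011113
T[C>G]C	0.00000000000000000	0.00000000000000000	0.000000
T[C>G]G	0.00010800010800011	0.00000000000000000	0.000000
T[C>G]T	0.00000700000700001	0.09825709825709826	0.000000
A[C>T]A	0.00000000000000000	0.00000500000500001	0.000000
A[C>T]C	0.00000000000000000	0.05600205600205601	0.000000
A[C>T]G	0.00000100000100000	0.00000000000000000	0.000000
A[C>T]T	0.00004700004700005	0.00000000000000000	0.000004
C[C>T]A	0.00000000000000000	0.00000000000000000	0.000000
C[C>T]C	0.00138200138200138	0.13424113424113424	0.014955
C[C>T]G	0.00000000000000000	0.00000000000000000	0.000000
C[C>T]T	0.01940401940401941	0.00000000000000000	0.000001
G[C>T]A	0.00000000000000000	0.00000000000000000	0.000000
G[C>T]C	0.00000300000300000	0.00484400484400484	0.024786
G[C>T]G	0.00000000000000000	0.12670512670512671	0.000001
G[C>T]T	0.01606701606701607	0.00000000000000000	0.000000
T[C>T]A	0.00000000000000000	0.00000000000000000	0.002094
T[C>T]C	0.00001800001800002	0.00000000000000000	0.000000
T[C>T]G	0.00000000000000000	0.00000000000000000	0.000003
T[C>T]T	0.00108700108700109	0.00000000000000000	0.000000
A[T>A]A	0.18785318785318786	0.00000000000000000	0.000000
A[T>A]C	0.00000000000000000	0.00000000000000000	0.000000
A[T>A]G	0.00005400005400005	0.00000000000000000	0.000000
A[T>A]T	0.00000000000000000	0.00000000000000000	0.000000
C[T>A]A	0.01208801208801209	0.00174700174700175	0.000000
C[T>A]C	0.21954121954121952	0.00000000000000000	0.000000
C[T>A]G	0.00000000000000000	0.00000000000000000	0.000000
C[T>A]T	0.00000000000000000	0.00015800015800016	0.026208
G[T>A]A	0.00000000000000000	0.00000000000000000	0.000000
G[T>A]C	0.00427300427300427	0.00000000000000000	0.000001
G[T>A]G	0.00000000000000000	0.06236806236806237	0.001751
G[T>A]T	0.00030700030700031	0.00000000000000000	0.000000
T[T>A]A	0.00000000000000000	0.00004800004800005	0.001871
T[T>A]C	0.00000000000000000	0.00000000000000000	0.000000
T[T>A]G	0.00000000000000000	0.00007800007800008	0.000000
T[T>A]T	0.00000000000000000	0.00006400006400006	0.030078
A[T>C]A	0.00000000000000000	0.00000000000000000	0.003853
A[T>C]C	0.00001900001900002	0.00009500009500010	0.000000
A[T>C]G	0.00358400358400358	0.00000000000000000	0.000000
A[T>C]T	0.00000000000000000	0.00000000000000000	0.000000
C[T>C]A	0.00202300202300202	0.00000000000000000	0.000000
C[T>C]C	0.00000000000000000	0.01362901362901363	0.000000
C[T>C]G	0.00528400528400528	0.00000000000000000	0.000000
C[T>C]T	0.00000000000000000	0.00000000000000000	0.000000
G[T>C]A	0.00000000000000000	0.03690703690703691	0.000000
G[T>C]C	0.00000000000000000	0.00214400214400214	0.000044
G[T>C]G	0.00131100131100131	0.00000000000000000	0.000001
G[T>C]T	0.00000000000000000	0.00000000000000000	0.000000
T[T>C]A	0.00000000000000000	0.00000000000000000	0.078687
T[T>C]C	0.00000300000300000	0.00000000000000000	0.000000
T[T>C]G	0.00000000000000000	0.00107300107300107	0.000000
T[T>C]T	0.00000000000000000	0.00000000000000000	0.000000
A[T>G]A	0.07075307075307075	0.00000000000000000	0.000003
A[T>G]C	0.00000000000000000	0.00000100000100000	0.000000
A[T>G]G	0.00000000000000000	0.00000000000000000	0.000198
A[T>G]T	0.00000000000000000	0.03435103435103435	0.065504
C[T>G]A	0.00000000000000000	0.00000000000000000	0.000000
C[T>G]C	0.00000000000000000	0.00000000000000000	0.000000
C[T>G]G	0.00000700000700001	0.00000100000100000	0.000000
C[T>G]T	0.00000000000000000	0.00000000000000000	0.000590
G[T>G]A	0.00000000000000000	0.00000000000000000	0.067454
G[T>G]C	0.00000000000000000	0.00379100379100379	0.000031
G[T>G]G	0.00000200000200000	0.00004700004700005	0.000000
G[T>G]T	0.00765200765200765	0.00000000000000000	0.000225
T[T>G]A	0.00004700004700005	0.01198701198701199	0.000000
T[T>G]C	0.00000000000000000	0.00000000000000000	0.000000
T[T>G]G	0.00000000000000000	0.00000000000000000	0.019500
T[T>G]T	0.06187406187406187	0.00000100000100000	0.000125
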
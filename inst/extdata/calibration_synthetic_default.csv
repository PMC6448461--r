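let_keV_um,response_S
             3.5,0.0065479004268544
3.98033957362621,0.00794109125517705
 4.5266008918214,0.00963071003102346
5.14783104677955,0.0116798274596314
5.85431875252522,0.0141649337429239
6.65776474494234,0.017178793833634
7.57147556748212,0.0208339101992569
8.61058395199801,0.0252667223551446
9.79229944461956,0.0306426999284433
11.1361934274906,0.0371625193686206
12.6645232568563,0.0450695548710828
14.4026008858213,0.054658963137809
 16.379212076851,0.0662887010942555
18.6270931469447,0.0803928878358834
21.1834731412588,0.0974980095839138
24.0906904145715,0.118242572554807
27.3968938323133,0.143400937352937
31.1568402043407,0.173912224585349
35.4328011584244,0.210915370697926
40.2955944729444,0.255791642609987
45.8257569495584,0.310216198149085
52.1148782507725,0.376220616952694
59.2671177932176,0.45626873601308
67.4009298191744,0.553348620682182
76.6510252167036,0.671084104263711
87.1706025797331,0.813870059782963
99.1338854585586,0.987036453408279
112.739007822294,1.19704730337002
128.211295521838,1.45174197118809
145.806998100416,1.76062779221483
165.817532757351,2.13523496891285
188.574310752898,2.58954697445327
214.454226188299,3.14052253289684
243.885898065335,3.80872866062417
277.356769005378,4.61910839941631
315.421178195774,5.60191189940577
358.709542266413,6.79382560770156
407.938796148671, 8.2393417134528
463.924266836569,9.99241896849486
527.593176701463,12.1184968792966
             600,14.6969384566991
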
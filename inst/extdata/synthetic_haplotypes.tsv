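category	frequency
A*05:01~C*04:01~B*02:01~DRB3*03:01~DRB1*03:01~DQB1*03:01	0.0971920659753716
A*02:01~C*01:01~B*02:01~DRB3*01:01~DRB1*03:01~DQB1*04:01	0.0971545241440311
A*02:01~C*03:01~B*07:01~DRB3*03:01~DRB1*01:01~DQB1*02:01	0.0740637177738526
A*06:01~C*02:01~B*08:01~DRB4*02:01~DRB1*03:01~DQB1*01:01	0.0582084363569386
A*06:01~C*03:01~B*08:01~DRB3*02:01~DRB1*01:01~DQB1*02:01	0.0546324795588004
A*07:01~C*04:01~B*01:01~DRB4*02:01~DRB1*01:01~DQB1*01:01	0.0517164557530035
A*05:01~C*01:01~B*06:01~DRB3*01:01~DRB1*05:01~DQB1*05:01	0.0488676866979063
A*01:01~C*01:01~B*02:01~DRB3*02:01~DRB1*02:01~DQB1*01:01	0.0486778103691182
A*06:01~C*01:01~B*04:01~DRB3*03:01~DRB1*05:01~DQB1*03:01	0.0440693543285702
A*05:01~C*06:01~B*05:01~DRB4*02:01~DRB1*02:01~DQB1*02:01	0.0348290481426308
A*03:01~C*05:01~B*01:01~DRB4*02:01~DRB1*06:01~DQB1*02:01	0.0313984905348176
A*01:01~C*04:01~B*08:01~DRB3*01:01~DRB1*02:01~DQB1*02:01	0.0304834310762043
A*05:01~C*05:01~B*05:01~DRB3*03:01~DRB1*06:01~DQB1*02:01	0.0268443575598292
A*08:01~C*05:01~B*08:01~DRB3*03:01~DRB1*01:01~DQB1*04:01	0.0257575636937025
A*06:01~C*06:01~B*05:01~DRB3*03:01~DRB1*05:01~DQB1*01:01	0.0226194646803103
A*07:01~C*03:01~B*07:01~DRB4*01:01~DRB1*04:01~DQB1*01:01	0.020246533634554
A*05:01~C*01:01~B*05:01~DRB4*01:01~DRB1*05:01~DQB1*02:01	0.0176749742668781
A*02:01~C*04:01~B*07:01~DRB4*01:01~DRB1*04:01~DQB1*04:01	0.016659059985858
A*08:01~C*02:01~B*06:01~DRB4*02:01~DRB1*02:01~DQB1*04:01	0.016575538520207
A*01:01~C*05:01~B*08:01~DRB4*02:01~DRB1*03:01~DQB1*03:01	0.0154996607864195
A*06:01~C*04:01~B*06:01~DRB4*02:01~DRB1*01:01~DQB1*05:01	0.0144639361335606
A*06:01~C*02:01~B*03:01~DRB3*02:01~DRB1*04:01~DQB1*03:01	0.014100586869813
A*07:01~C*01:01~B*07:01~DRB4*01:01~DRB1*04:01~DQB1*03:01	0.0140662602304131
A*05:01~C*04:01~B*01:01~DRB4*01:01~DRB1*01:01~DQB1*03:01	0.0137516003128751
A*05:01~C*06:01~B*05:01~DRB4*01:01~DRB1*03:01~DQB1*01:01	0.0115618601603922
A*01:01~C*06:01~B*04:01~DRB3*03:01~DRB1*03:01~DQB1*04:01	0.0105464377010414
A*06:01~C*04:01~B*02:01~DRB3*02:01~DRB1*07:01~DQB1*01:01	0.0098938021820066
A*07:01~C*05:01~B*02:01~DRB4*02:01~DRB1*03:01~DQB1*05:01	0.00947079029339165
A*03:01~C*02:01~B*06:01~DRB4*01:01~DRB1*01:01~DQB1*04:01	0.0090314979362011
A*05:01~C*01:01~B*04:01~DRB4*01:01~DRB1*04:01~DQB1*05:01	0.0072802714449721
A*08:01~C*02:01~B*04:01~DRB4*02:01~DRB1*03:01~DQB1*03:01	0.00720720928186771
A*05:01~C*06:01~B*06:01~DRB4*02:01~DRB1*07:01~DQB1*01:01	0.00710215068389604
A*04:01~C*04:01~B*08:01~DRB3*02:01~DRB1*04:01~DQB1*05:01	0.00593654380068142
A*07:01~C*02:01~B*07:01~DRB4*02:01~DRB1*02:01~DQB1*02:01	0.00575977840278884
A*08:01~C*04:01~B*05:01~DRB3*02:01~DRB1*03:01~DQB1*01:01	0.00554084948108969
A*05:01~C*01:01~B*08:01~DRB3*03:01~DRB1*01:01~DQB1*03:01	0.00504597645964331
A*02:01~C*01:01~B*08:01~DRB4*02:01~DRB1*02:01~DQB1*03:01	0.00499748434656241
A*01:01~C*01:01~B*07:01~DRB4*02:01~DRB1*02:01~DQB1*02:01	0.00378062943753613
A*06:01~C*01:01~B*04:01~DRB4*02:01~DRB1*02:01~DQB1*02:01	0.00367945023068798
A*01:01~C*05:01~B*05:01~DRB3*03:01~DRB1*02:01~DQB1*02:01	0.0036122307715757
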
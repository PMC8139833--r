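chrX	0	118200
chrX	267000	289200
chrX	321000	328800
chrX	402000	559200
chrX	753600	835800
chrX	843600	948000
chrX	997800	1215600
chrX	1662000	2092200
chrX	2185800	2276400
chrX	2320200	2373600
chrX	2430600	2511000
chrX	2537400	2676600
chrX	2849400	2854200
chrX	2995800	3055200
chrX	3206400	3307800
chrX	3321600	3359400
chrX	3373200	3402600
chrX	3418800	3463200
chrX	3471600	3666000
chrX	3687000	3793800
chrX	3796200	3811800
chrX	3835200	3891000
chrX	3939600	4062600
chrX	4270800	4285200
chrX	4356600	4390200
chrX	4390800	4413600
chrX	4435200	4544400
chrX	4558200	4630200
chrX	4830000	4951800
chrX	5032800	5071800
chrX	5222400	5281200
chrX	5485800	5613600
chrX	5671200	5673000
chrX	6622800	6756600
chrX	6912000	6925800
chrX	6969000	7065600
chrX	7227600	7841400
chrX	8019600	8088000
chrX	8092200	8132400
chrX	8206200	8233800
chrX	8418600	8506800
chrX	8512800	8567400
chrX	8581200	8706600
chrX	8941200	9451200
chrX	9630000	9645600
chrX	10011000	10020000
chrX	10064400	10253400
chrX	10437600	10587600
chrX	10594800	10599600
chrX	10680000	10713000
chrX	11069400	11103000
chrX	11271000	11382000
chrX	11626200	11677800
chrX	11710800	11743800
chrX	11754000	11791800
chrX	11928000	11965200
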
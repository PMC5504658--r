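series,day,observed,arima,ses,l1
EOV,1,206,194.40,196.76,0.53
EOV,2,193,189.47,195.68,0.57
EOV,3,182,194.27,190.00,0.58
EOV,4,171,248.46,256.56,0.57
EOV,5,150,197.90,193.76,0.46
EOV,6,86,66.11,76.33,0.39
EOV,7,34,41.00,46.28,0.46
ROV,1,173,197.32,186.12,0.52
ROV,2,178,197.88,196.28,0.55
ROV,3,145,160.23,177.78,0.51
ROV,4,161,174.97,185.36,0.50
ROV,5,163,121.83,126.76,0.48
ROV,6,18,24.85,27.32,0.28
ROV,7,11,18.03,13.61,0.36
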
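image_id	x	y
frame01	343.659232485108	192.193191289436
frame01	118.081571520772	93.4449136941694
frame01	230.092791953124	256.284000558546
frame01	274.334296267014	95.138375329785
frame01	251.747618040768	125.371055109659
frame01	373.769877469866	129.066622518701
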
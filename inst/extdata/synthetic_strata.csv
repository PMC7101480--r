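region_id,facility_type,x_successes,n_x,readiness_kind,y_successes,n_y,y_mean,y_var,region_weight
region_01,ftype_1,66,400,binary,25,60,,,0.7937836919445544
region_01,ftype_2,98,400,binary,24,60,,,0.7937836919445544
region_01,ftype_3,52,400,binary,28,60,,,0.7937836919445544
region_01,ftype_4,69,400,binary,36,60,,,0.7937836919445544
region_01,ftype_5,62,400,binary,33,60,,,0.7937836919445544
region_02,ftype_1,65,400,binary,22,60,,,0.6443818469997495
region_02,ftype_2,99,400,binary,14,60,,,0.6443818469997495
region_02,ftype_3,46,400,binary,54,60,,,0.6443818469997495
region_02,ftype_4,42,400,binary,42,60,,,0.6443818469997495
region_02,ftype_5,105,400,binary,23,60,,,0.6443818469997495
region_03,ftype_1,91,400,binary,38,60,,,0.8551735745277256
region_03,ftype_2,100,400,binary,18,60,,,0.8551735745277256
region_03,ftype_3,39,400,binary,18,60,,,0.8551735745277256
region_03,ftype_4,69,400,binary,37,60,,,0.8551735745277256
region_03,ftype_5,67,400,binary,41,60,,,0.8551735745277256
region_04,ftype_1,76,400,binary,40,60,,,0.8413785169832408
region_04,ftype_2,36,400,binary,32,60,,,0.8413785169832408
region_04,ftype_3,96,400,binary,40,60,,,0.8413785169832408
region_04,ftype_4,42,400,binary,32,60,,,0.8413785169832408
region_04,ftype_5,117,400,binary,45,60,,,0.8413785169832408
region_05,ftype_1,96,400,binary,44,60,,,1.4889845817815512
region_05,ftype_2,79,400,binary,46,60,,,1.4889845817815512
region_05,ftype_3,55,400,binary,25,60,,,1.4889845817815512
region_05,ftype_4,45,400,binary,55,60,,,1.4889845817815512
region_05,ftype_5,77,400,binary,17,60,,,1.4889845817815512
region_06,ftype_1,51,400,binary,42,60,,,1.05081255431287
region_06,ftype_2,99,400,binary,9,60,,,1.05081255431287
region_06,ftype_3,106,400,binary,13,60,,,1.05081255431287
region_06,ftype_4,51,400,binary,54,60,,,1.05081255431287
region_06,ftype_5,45,400,binary,32,60,,,1.05081255431287
region_07,ftype_1,43,400,binary,27,60,,,1.0930213269311935
region_07,ftype_2,106,400,binary,14,60,,,1.0930213269311935
region_07,ftype_3,69,400,binary,30,60,,,1.0930213269311935
region_07,ftype_4,90,400,binary,44,60,,,1.0930213269311935
region_07,ftype_5,52,400,binary,39,60,,,1.0930213269311935
region_08,ftype_1,68,400,binary,47,60,,,0.8603122949134558
region_08,ftype_2,89,400,binary,24,60,,,0.8603122949134558
region_08,ftype_3,102,400,binary,14,60,,,0.8603122949134558
region_08,ftype_4,55,400,binary,17,60,,,0.8603122949134558
region_08,ftype_5,47,400,binary,44,60,,,0.8603122949134558
region_09,ftype_1,95,400,binary,32,60,,,0.5204922575503588
region_09,ftype_2,88,400,binary,46,60,,,0.5204922575503588
region_09,ftype_3,36,400,binary,12,60,,,0.5204922575503588
region_09,ftype_4,82,400,binary,17,60,,,0.5204922575503588
region_09,ftype_5,68,400,binary,46,60,,,0.5204922575503588
region_10,ftype_1,66,400,binary,48,60,,,1.4885252208914608
region_10,ftype_2,93,400,binary,16,60,,,1.4885252208914608
region_10,ftype_3,83,400,binary,43,60,,,1.4885252208914608
region_10,ftype_4,70,400,binary,42,60,,,1.4885252208914608
region_10,ftype_5,56,400,binary,49,60,,,1.4885252208914608
region_11,ftype_1,86,400,binary,34,60,,,1.4646606375463307
region_11,ftype_2,110,400,binary,40,60,,,1.4646606375463307
region_11,ftype_3,44,400,binary,29,60,,,1.4646606375463307
region_11,ftype_4,40,400,binary,25,60,,,1.4646606375463307
region_11,ftype_5,89,400,binary,38,60,,,1.4646606375463307
region_12,ftype_1,46,400,binary,46,60,,,1.0138600717764348
region_12,ftype_2,69,400,binary,16,60,,,1.0138600717764348
region_12,ftype_3,105,400,binary,41,60,,,1.0138600717764348
region_12,ftype_4,62,400,binary,11,60,,,1.0138600717764348
region_12,ftype_5,76,400,binary,34,60,,,1.0138600717764348
region_13,ftype_1,32,400,binary,39,60,,,0.900577288819477
region_13,ftype_2,88,400,binary,49,60,,,0.900577288819477
region_13,ftype_3,33,400,binary,26,60,,,0.900577288819477
region_13,ftype_4,102,400,binary,26,60,,,0.900577288819477
region_13,ftype_5,109,400,binary,13,60,,,0.900577288819477
region_14,ftype_1,80,400,binary,44,60,,,0.5549154351465404
region_14,ftype_2,90,400,binary,25,60,,,0.5549154351465404
region_14,ftype_3,46,400,binary,33,60,,,0.5549154351465404
region_14,ftype_4,105,400,binary,47,60,,,0.5549154351465404
region_14,ftype_5,42,400,binary,33,60,,,0.5549154351465404
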
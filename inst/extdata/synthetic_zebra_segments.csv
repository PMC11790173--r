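"id","x1","y1","x2","y2","length_stage_a","length_stage_b"
"seg1",178.813148264308,192.889428494964,162.316869108867,199,44.3574981018901,55.7501091242457
"seg2",183.044328526594,184.866964186076,199,175.688548992802,53.4720623772591,102.434029449763
"seg3",59.3665116094053,20.6631360389292,82.8160868054238,2,50.0609025079757,150.296823554692
"seg4",162.785048952792,102.700239026453,151.809169977715,89.4362833907755,38.1092629022896,38.1365754200579
"seg5",126.931648589671,79.138658749871,138.033984969622,77.090577344435,41.4315997529775,67.3557606827007
"seg6",103.628230334725,177.090244872961,93.1956455621172,167.435734542175,41.4950678125024,157.64401096922
"seg7",144.951779781841,89.9242293392308,136.697575651871,104.201475091797,20.0552337430418,75.7472991323025
"seg8",30.586653475184,163.840809399262,16.6612789608635,183.854898641124,34.2266381531954,109.603378185743
"seg9",129.828535176348,145.143167376518,117.036760927146,154.624226169926,44.485323606059,88.9357685056252
"seg10",138.96230896702,159.100476840977,145.791913491683,128.267125681579,53.1576852221042,135.296408292179
"seg11",91.9709374872036,78.7405737349764,101.902669465981,81.2199880481848,34.2688799742609,110.754413550219
"seg12",141.631327813957,135.182248586789,141.470380844042,113.918158739901,36.4254050329328,104.084783328257
"seg13",182.587726959027,5.75018437113613,171.367078242714,2,42.9390359576792,123.61015005813
"seg14",53.5314766247757,163.254055248108,58.3016179883259,172.096583386521,43.5871321428567,71.9829760094632
"seg15",92.835636283271,6.39348790748045,90.9249345306701,33.7750239213619,48.7862916942686,80.4828397075865
"seg16",183.602759323549,44.4552048365586,168.92599118875,43.1224440483982,35.7989218086004,77.5703598142177
"seg17",190.863021393307,177.254267481621,181.503937172351,158.711459764696,56.7681571654975,217.272575697681
"seg18",27.3225987143815,121.237942255102,56.5205596983701,118.0733456631,58.5028117429465,227.448637978065
"seg19",95.2494454965927,77.1162557019852,97.2436803410794,43.9013682871542,29.3409410212189,94.465091356245
"seg20",111.463221786544,87.7966011455283,86.8680145816541,76.8790980753501,48.979903999716,156.722846210997
"seg21",176.765963586513,12.1118962438777,186.737989144707,2,56.1453810054809,146.386946270094
"seg22",31.3549318676814,189.972583616618,36.0689013492928,199,44.1389633901417,44.4399424905805
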
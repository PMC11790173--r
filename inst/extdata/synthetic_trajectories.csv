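"id","stage","length"
"head",1,17.7384087343431
"head",2,18.2786237054246
"head",3,18.835290671685
"head",4,19.4089106709702
"head",5,20
"head",6,20.6090906790703
"head",7,21.2367309309072
"head",8,21.8834856741042
"head",9,22.5499370315875
"head",10,23.2366848545657
"d1",1,17.5637223244235
"d1",2,19.7356724981767
"d1",3,22.1762085371657
"d1",4,24.918544079473
"d1",5,28
"d1",6,31.4625123161121
"d1",7,35.3532029014822
"d1",8,39.7250207750676
"d1",9,44.6374626926204
"d1",10,50.1573828473772
"d2",1,22.5016102277725
"d2",2,25.3067178678448
"d2",3,28.4615173207581
"d2",4,32.0096020523106
"d2",5,36
"d2",6,40.4878510480091
"d2",7,45.5351689579381
"d2",8,51.2116982837479
"d2",9,57.5958781118881
"d2",10,64.7759259437059
"d3",1,30.520766120708
"d3",2,33.4433475626215
"d3",3,36.6457870608772
"d3",4,40.154883024093
"d3",5,44
"d3",6,48.2133144015983
"d3",7,52.8300837633492
"d3",8,57.8889417805711
"d3",9,63.4322216009658
"d3",10,69.5063100736186
"d4",1,33.061587117043
"d4",2,37.0248757183721
"d4",3,41.4632672384393
"d4",4,46.4337150828883
"d4",5,52
"d4",6,58.2335485147618
"d4",7,65.214349473483
"d4",8,73.031980460052
"d4",9,81.7867572547995
"d4",10,91.5910210858156
"d5",1,39.3173256986932
"d5",2,43.6994318098873
"d5",3,48.5699448416569
"d5",4,53.9833001075278
"d5",5,60
"d5",6,66.6872901958432
"d5",7,74.1199112277434
"d5",8,82.3809338222443
"d5",9,91.5626873401427
"d5",10,101.767791696056
"d6",1,45.4427073459741
"d6",2,50.2603346907495
"d6",3,55.588704783672
"d6",4,61.4819642276473
"d6",5,68
"d6",6,75.2090480206336
"d6",7,83.1823662377937
"d6",8,92.0009790712964
"d6",9,101.754500778212
"d6",10,112.542046108003
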
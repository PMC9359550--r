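"observer","session","pass_id","trial","pair","interval","mu_cloud","sigma_cloud","n_dots","dot_x","dot_y","centroid","sigma_emp","true_side","r","conf_choice"
"synthetic01",1,1,1,1,1,-2,2,2,"-4.61953891949454;-1.15187175701574","3.36445473684588;0.650161031565668",-2.88570533825514,1.7338335812394,-1,-1,2
"synthetic01",1,1,2,1,2,2,2,5,"-1.07518382728819;6.64918691867537;2.82287243726714;-0.348677675623916;5.44596963046265","-0.307335205445214;1.97755153365184;1.59619178711085;0.0340590306943757;-1.87342851693884",2.69883349669861,3.05607479823109,1,1,NA
"synthetic01",1,1,3,2,1,2,2,2,"2.56546176430123;5.42358739319177","-3.68548585278006;-0.976173693391678",3.9945245787465,1.42906281444527,1,1,2
"synthetic01",1,1,4,2,2,-2,2,5,"2.45050290927542;-1.93254832042664;-0.879093278550138;-5.92235314716697;-4.06992396363731","-0.947917932810883;0.895255457019229;4.97958820399657;2.59931300639853;0.78184648732853",-2.07068316010113,2.85350369312741,-1,-1,NA
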
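# Synthetic fixture: jointly satisficing (summary statistic = 0) parameter sets.
# Generated by make_satisficing_params(k = 12, seed = 20, cfg = model_config())
# (Sobol' draws over the log10 [-4,4]^8 prior box, default configuration).
# Columns are log10 values.
"K1","K3","K4","alpha","K6","K7","beta","K9"
-0.792328890413046,1.33576566912234,0.794205106794834,2.92080954089761,-3.1092437505722,3.40533667989075,-1.9568392932415,2.25349582731724
2.29360860958695,3.40607816912234,0.114517606794834,3.41299704089761,-0.882681250572205,3.61627417989075,-2.1052767932415,-3.41056667268276
0.328764859586954,-0.105640580877662,-3.04563864320517,3.70596579089761,-3.7615875005722,3.20611792989075,-2.5076205432415,-0.250410422682762
0.320952359586954,-2.12907808087766,0.602798856794834,2.55752829089761,-2.3319000005722,0.713930429890752,-1.4060580432415,-3.57072292268276
3.67446798458695,3.52521879412234,2.34693948179483,3.45010641589761,-2.0291656255722,-2.38958519510925,-1.6306674182415,-3.90470729768276
1.69009298458695,2.75959379412234,1.67506448179483,3.65323141589761,-1.8260406255722,2.93853980489075,-1.9587924182415,-0.0765822976827621
1.21743673458695,2.84162504412234,1.08522073179483,2.90713766589761,1.4981781244278,2.54400855489075,-1.4314486682415,-3.04923854768276
2.75649923458695,1.94318754412234,3.04615823179483,2.58682516589761,1.7403656244278,3.27057105489075,-1.6267611682415,-1.63517604768276
3.36685079708695,-0.680835893377662,1.94947854429483,2.97842672839761,-2.6336578130722,3.34186011739075,-1.7566439807415,-0.395918235182762
2.53872579708695,1.42853910662234,-1.34739645570517,3.93155172839761,-3.2742828130722,3.66998511739075,-1.3972689807415,1.08845676481724
0.109038297086954,-0.282398393377662,0.722916044294834,3.26748922839761,-0.125845313072205,1.22467261739075,-1.5769564807415,-3.02873073518276
0.839507047086954,3.48713285662234,-0.343490205705166,3.64639547839761,-3.5047515630722,-0.763608632609248,-1.3543002307415,-1.80607448518276
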
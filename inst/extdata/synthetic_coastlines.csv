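polygon,lon,lat
north_america,-168,66
north_america,-164,60
north_america,-158,57
north_america,-152,59
north_america,-145,60
north_america,-135,57
north_america,-128,52
north_america,-124,48
north_america,-124,40
north_america,-117,33
north_america,-110,24
north_america,-105,20
north_america,-97,16
north_america,-92,15
north_america,-90,13
north_america,-85,11
north_america,-83,9
north_america,-80,8
north_america,-77,8
north_america,-81,12
north_america,-84,16
north_america,-88,18
north_america,-87,21
north_america,-91,19
north_america,-97,21
north_america,-97,28
north_america,-91,29
north_america,-84,30
north_america,-81,25
north_america,-80,27
north_america,-81,31
north_america,-76,35
north_america,-74,40
north_america,-70,42
north_america,-66,44
north_america,-60,46
north_america,-64,49
north_america,-58,51
north_america,-60,55
north_america,-64,58
north_america,-70,58
north_america,-77,62
north_america,-83,66
north_america,-92,66
north_america,-95,69
north_america,-105,68
north_america,-115,69
north_america,-128,70
north_america,-140,70
north_america,-155,71
north_america,-162,70
north_america,-168,66
south_america,-77,8
south_america,-75,11
south_america,-71,12
south_america,-64,10
south_america,-60,8
south_america,-52,5
south_america,-50,0
south_america,-44,-3
south_america,-35,-6
south_america,-35,-10
south_america,-39,-15
south_america,-40,-22
south_america,-48,-26
south_america,-52,-33
south_america,-57,-36
south_america,-62,-39
south_america,-65,-41
south_america,-65,-46
south_america,-68,-51
south_america,-69,-55
south_america,-73,-53
south_america,-74,-46
south_america,-73,-40
south_america,-71,-33
south_america,-70,-25
south_america,-70,-18
south_america,-75,-15
south_america,-79,-8
south_america,-81,-4
south_america,-80,0
south_america,-78,4
south_america,-77,8
afro_eurasia,-10,44
afro_eurasia,-9,39
afro_eurasia,-6,36
afro_eurasia,-10,32
afro_eurasia,-15,27
afro_eurasia,-17,21
afro_eurasia,-17,15
afro_eurasia,-16,11
afro_eurasia,-12,8
afro_eurasia,-8,5
afro_eurasia,-4,5
afro_eurasia,2,6
afro_eurasia,8,4
afro_eurasia,9,0
afro_eurasia,12,-5
afro_eurasia,13,-11
afro_eurasia,14,-17
afro_eurasia,15,-23
afro_eurasia,17,-30
afro_eurasia,20,-35
afro_eurasia,26,-34
afro_eurasia,30,-31
afro_eurasia,33,-27
afro_eurasia,36,-22
afro_eurasia,38,-17
afro_eurasia,40,-11
afro_eurasia,40,-5
afro_eurasia,42,-1
afro_eurasia,45,2
afro_eurasia,49,7
afro_eurasia,51,11
afro_eurasia,44,11
afro_eurasia,43.5,12.5
afro_eurasia,45,13
afro_eurasia,48,14
afro_eurasia,52,16
afro_eurasia,55,17.5
afro_eurasia,58,20
afro_eurasia,59.5,22.5
afro_eurasia,58,26
afro_eurasia,61,25.5
afro_eurasia,64,25.3
afro_eurasia,66.5,25
afro_eurasia,67,24
afro_eurasia,70,21
afro_eurasia,72,18
afro_eurasia,73,13
afro_eurasia,77,8
afro_eurasia,80,10
afro_eurasia,80,14
afro_eurasia,84,19
afro_eurasia,87,21
afro_eurasia,91,22
afro_eurasia,92,18
afro_eurasia,94,16
afro_eurasia,97,13
afro_eurasia,98,8
afro_eurasia,101,3
afro_eurasia,104,2
afro_eurasia,103,7
afro_eurasia,100,12
afro_eurasia,100,15
afro_eurasia,104,11
afro_eurasia,107,11
afro_eurasia,108,16
afro_eurasia,106,20
afro_eurasia,110,21
afro_eurasia,114,22
afro_eurasia,118,24
afro_eurasia,121,29
afro_eurasia,122,32
afro_eurasia,120,35
afro_eurasia,122,37
afro_eurasia,122,40
afro_eurasia,125,39
afro_eurasia,127,36
afro_eurasia,130,35
afro_eurasia,130,39
afro_eurasia,128,41
afro_eurasia,132,43
afro_eurasia,135,45
afro_eurasia,137,49
afro_eurasia,139,54
afro_eurasia,143,59
afro_eurasia,153,60
afro_eurasia,160,61
afro_eurasia,170,65
afro_eurasia,179,68
afro_eurasia,179,71
afro_eurasia,170,70
afro_eurasia,160,71
afro_eurasia,150,72
afro_eurasia,140,73
afro_eurasia,128,72
afro_eurasia,115,74
afro_eurasia,105,77
afro_eurasia,95,76
afro_eurasia,85,74
afro_eurasia,75,72
afro_eurasia,68,69
afro_eurasia,60,69
afro_eurasia,52,68
afro_eurasia,44,68
afro_eurasia,40,66
afro_eurasia,35,65
afro_eurasia,30,70
afro_eurasia,25,71
afro_eurasia,18,70
afro_eurasia,12,65
afro_eurasia,5,62
afro_eurasia,6,58
afro_eurasia,10,57
afro_eurasia,8,55
afro_eurasia,4,52
afro_eurasia,0,49
afro_eurasia,-2,47
afro_eurasia,-10,44
mediterranean_sea,-5.5,36
mediterranean_sea,0,38
mediterranean_sea,5,40
mediterranean_sea,8,42
mediterranean_sea,12,43
mediterranean_sea,15,40
mediterranean_sea,19,40
mediterranean_sea,22,38
mediterranean_sea,26,38.5
mediterranean_sea,28,36.5
mediterranean_sea,32,36
mediterranean_sea,35,35.5
mediterranean_sea,35.5,34
mediterranean_sea,34,31.5
mediterranean_sea,30,31.5
mediterranean_sea,25,32
mediterranean_sea,20,31.5
mediterranean_sea,15,33
mediterranean_sea,10,34.5
mediterranean_sea,5,36
mediterranean_sea,0,36
mediterranean_sea,-5.5,35.8
mediterranean_sea,-5.5,36
red_sea,33,29.5
red_sea,35,27
red_sea,37,24
red_sea,39,21
red_sea,41,18
red_sea,43,14
red_sea,43.5,12.5
red_sea,42,13.5
red_sea,40,17
red_sea,38,20
red_sea,36,23
red_sea,34,26
red_sea,32.5,28.5
red_sea,33,29.5
australia,114,-22
australia,115,-30
australia,115,-34
australia,119,-35
australia,124,-33
australia,130,-32
australia,136,-35
australia,140,-38
australia,147,-39
australia,150,-37
australia,153,-32
australia,153,-26
australia,149,-21
australia,146,-19
australia,143,-14
australia,142,-11
australia,137,-12
australia,132,-11
australia,127,-14
australia,122,-17
australia,118,-20
australia,114,-22
greenland,-45,60
greenland,-50,63
greenland,-53,66
greenland,-54,70
greenland,-57,74
greenland,-67,76
greenland,-62,80
greenland,-50,82
greenland,-35,83
greenland,-25,82
greenland,-20,79
greenland,-19,75
greenland,-22,70
greenland,-32,66
greenland,-40,63
greenland,-45,60
antarctica,-179,-64
antarctica,179,-64
antarctica,179,-89
antarctica,-179,-89
antarctica,-179,-64
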
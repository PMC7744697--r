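{"latents":[{"MJrisk":1.28922560030101,"SSscore":1.17116087340933,"Compliance":0.231655111891968,"pMSV":1.6963154067852,"pAS":1.44716617846139,"AdLike":0.278763671712538,"pos":-1.00710325602376,"neg":0.532718814980923,"ThVal":-1.2090135137912,"_row":"s01"},{"MJrisk":-1.39035657261121,"SSscore":-0.486167649215537,"Compliance":-1.32057243243556,"pMSV":-0.445283664259466,"pAS":-0.00797513448459304,"AdLike":-0.330873235369178,"pos":0.503301349091249,"neg":0.0820215669715592,"ThVal":1.16317171067099,"_row":"s02"},{"MJrisk":-0.105940965612554,"SSscore":0.602917152041376,"Compliance":-1.17924247130302,"pMSV":-0.285791731787379,"pAS":0.977928460746851,"AdLike":0.87239111008034,"pos":0.0396283461360307,"neg":-2.27517738345346,"ThVal":0.0334351620694395,"_row":"s03"},{"MJrisk":0.267459424588398,"SSscore":1.38476106650549,"Compliance":1.28145651442448,"pMSV":-1.67250215319281,"pAS":-0.988745825322622,"AdLike":-0.723977740349432,"pos":-1.49671645651356,"neg":0.231156598113305,"ThVal":0.85460295591479,"_row":"s04"},{"MJrisk":-0.0489898652943276,"SSscore":-1.54225368788214,"Compliance":0.217007265549858,"pMSV":0.374799337421105,"pAS":-0.163340183755083,"AdLike":-1.41373079937049,"pos":1.78165667983285,"neg":-0.267451679997127,"ThVal":0.716961147656971,"_row":"s05"},{"MJrisk":-0.755540572732834,"SSscore":-0.658240208600475,"Compliance":-0.747928546117816,"pMSV":-0.638226587641282,"pAS":-0.22215424944473,"AdLike":0.522615280430203,"pos":0.485588521203002,"neg":0.154962509491941,"ThVal":0.483404109327708,"_row":"s06"},{"MJrisk":1.48381155109221,"SSscore":-0.542396212082624,"Compliance":0.305160792480847,"pMSV":0.370519908888912,"pAS":-1.60584106640048,"AdLike":-0.815025454218988,"pos":-0.282940338208509,"neg":0.458197133116597,"ThVal":-1.57810753864149,"_row":"s07"},{"MJrisk":-0.739668599730693,"SSscore":0.0702186658245797,"Compliance":1.21246376550925,"pMSV":0.600169483785716,"pAS":0.562961820199265,"AdLike":1.60983716708501,"pos":-0.0234148455173072,"neg":1.08357244077626,"ThVal":-0.464454033207214,"_row":"s08"}],"effects":{"MJrisk":0,"SSscore":5,"Compliance":0,"pMSV":0,"pAS":0,"AdLike":0,"pos":0,"neg":0,"ThVal":0},"drivers":{"6":"SSscore"},"noise_sd":1,"voxels_per_roi":25,"seed":42,"subjects":["s01","s02","s03","s04","s05","s06","s07","s08"]}
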
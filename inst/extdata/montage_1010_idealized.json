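{"channels":[{"label":"Fp1","x":-0.293892626146237,"y":0.904508497187474,"z":0.309016994374947},{"label":"Fpz","x":0,"y":0.951056516295154,"z":0.309016994374947},{"label":"Fp2","x":0.293892626146237,"y":0.904508497187474,"z":0.309016994374947},{"label":"F7","x":-0.769420884293813,"y":0.559016994374947,"z":0.309016994374947},{"label":"F3","x":-0.433027429173862,"y":0.645416362854495,"z":0.62922568617528},{"label":"Fz","x":0,"y":0.587785252292473,"z":0.809016994374947},{"label":"F4","x":0.433027429173862,"y":0.645416362854495,"z":0.62922568617528},{"label":"F8","x":0.769420884293813,"y":0.559016994374947,"z":0.309016994374947},{"label":"FC5","x":-0.753051997481352,"y":0.331827856739038,"z":0.568157515642733},{"label":"FC1","x":-0.28376368500327,"y":0.340738248458341,"z":0.896312231931991},{"label":"FC2","x":0.28376368500327,"y":0.340738248458341,"z":0.896312231931991},{"label":"FC6","x":0.753051997481352,"y":0.331827856739038,"z":0.568157515642733},{"label":"T7","x":-0.951056516295154,"y":5.82354159244546e-17,"z":0.309016994374947},{"label":"C3","x":-0.587785252292473,"y":3.59914663902998e-17,"z":0.809016994374947},{"label":"Cz","x":0,"y":0,"z":1},{"label":"C4","x":0.587785252292473,"y":3.59914663902998e-17,"z":0.809016994374947},{"label":"T8","x":0.951056516295154,"y":5.82354159244546e-17,"z":0.309016994374947},{"label":"CP5","x":-0.753051997481352,"y":-0.331827856739038,"z":0.568157515642733},{"label":"CP1","x":-0.28376368500327,"y":-0.340738248458341,"z":0.896312231931991},{"label":"CP2","x":0.28376368500327,"y":-0.340738248458341,"z":0.896312231931991},{"label":"CP6","x":0.753051997481352,"y":-0.331827856739038,"z":0.568157515642733},{"label":"P7","x":-0.769420884293813,"y":-0.559016994374947,"z":0.309016994374947},{"label":"P3","x":-0.433027429173862,"y":-0.645416362854495,"z":0.62922568617528},{"label":"Pz","x":7.19829327805997e-17,"y":-0.587785252292473,"z":0.809016994374947},{"label":"P4","x":0.433027429173862,"y":-0.645416362854494,"z":0.62922568617528},{"label":"P8","x":0.769420884293813,"y":-0.559016994374947,"z":0.309016994374947},{"label":"POz","x":9.90760072617092e-17,"y":-0.809016994374947,"z":0.587785252292473},{"label":"O1","x":-0.293892626146237,"y":-0.904508497187474,"z":0.309016994374947},{"label":"Oz","x":1.16470831848909e-16,"y":-0.951056516295154,"z":0.309016994374947},{"label":"O2","x":0.293892626146237,"y":-0.904508497187474,"z":0.309016994374947}],"blacklist":["Fp1","Fpz","Fp2","F7","F8","T7","T8","P7","P8","O1","Oz","O2"]}
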
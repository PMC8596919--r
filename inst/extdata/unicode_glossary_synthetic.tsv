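肺	lung
结节	nodule
肺结节	pulmonary nodule
胸膜	pleura
纵隔	mediastinum
支气管	bronchus
磨玻璃影	ground glass opacity
肺上叶	upper lobe of lung
肺下叶	lower lobe of lung
钙化	calcification
淋巴结	lymph node
胸腔积液	pleural effusion
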
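{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"label":"hippocampus"},"geometry":{"type":"Polygon","coordinates":[[[28000,13000],[27961.0876976105,12034.4011753993],[27844.603151655,11075.0646297069],[27651.3018091126,10128.2120285493],[27382.4373033657,9199.98407438233],[27039.7533239059,8296.4006816791],[26625.4723078385,7423.32193547478],[26142.2810265255,6586.41008646639],[25593.313160842,5791.09282914425],[24982.1289780532,5042.52810111046],[24312.6922421152,4345.57063187423],[23589.3445071445,3704.74045806815],[22816.7769607739,3124.19360927612],[22000,2607.69515458674],[21144.3107368367,2158.59478467541],[20255.2586445104,1779.80508777502],[19338.6095669974,1473.78266042353],[18400.3083253125,1242.51217549279],[17446.4401630639,1087.49351082335],[16483.191281313,1009.73202194116],[15516.808718687,1009.73202194116],[14553.5598369361,1087.49351082335],[13599.6916746875,1242.51217549279],[12661.3904330026,1473.78266042353],[11744.7413554896,1779.80508777502],[10855.6892631634,2158.59478467541],[10000,2607.69515458674],[9183.22303922613,3124.19360927612],[8410.65549285547,3704.74045806815],[7687.30775788481,4345.57063187423],[7017.87102194679,5042.52810111045],[6406.68683915799,5791.09282914425],[5857.71897347446,6586.41008646639],[5374.52769216148,7423.32193547478],[4960.24667609411,8296.4006816791],[4617.56269663426,9199.98407438232],[4348.69819088738,10128.2120285493],[4155.39684834505,11075.0646297069],[4038.91230238948,12034.4011753993],[4000,13000],[8000,13000],[8025.94153492632,12356.2674502662],[8103.5978988967,11716.7097531379],[8232.46546059159,11085.4746856995],[8411.70846442284,10466.6560495882],[8640.16445072941,9864.2671211194],[8916.35179477432,9282.21462364985],[9238.47931564964,8724.27339097759],[9604.45789277199,8194.06188609617],[10011.9140146312,7695.01873407364],[10458.2051719232,7230.38042124948],[10940.436995237,6803.16030537876],[11455.4820261508,6416.12907285075],[12000,6071.79676972449],[12570.4595087756,5772.39652311694],[13163.1609036597,5519.87005851668],[13774.2602886684,5315.85510694902],[14399.7944497916,5161.67478366186],[15035.7065579574,5058.32900721557],[15677.8724791247,5006.48801462744],[16322.1275208753,5006.48801462744],[16964.2934420426,5058.32900721557],[17600.2055502084,5161.67478366186],[18225.7397113316,5315.85510694902],[18836.8390963403,5519.87005851668],[19429.5404912244,5772.39652311694],[20000,6071.79676972449],[20544.5179738492,6416.12907285075],[21059.563004763,6803.16030537876],[21541.7948280768,7230.38042124948],[21988.0859853688,7695.01873407364],[22395.542107228,8194.06188609617],[22761.5206843504,8724.27339097759],[23083.6482052257,9282.21462364985],[23359.8355492706,9864.2671211194],[23588.2915355772,10466.6560495882],[23767.5345394084,11085.4746856995],[23896.4021011033,11716.7097531379],[23974.0584650737,12356.2674502662],[24000,13000],[28000,13000]]]}},{"type":"Feature","properties":{"label":"entorhinal"},"geometry":{"type":"Polygon","coordinates":[[[2000,14000],[30000,14000],[30000,20960],[2000,20960],[2000,14000]]]}}]}
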
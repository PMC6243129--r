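<?xml version="1.0" encoding="UTF-8"?>
<behavioralExperiment>
  <experimentDuration>60000</experimentDuration>
  <experimentDefinition>
    <experimentWideConf>
      <chemotaxis>
        <osmoticRingConf>
          <substanceId>glycerol</substanceId>
          <concentration>500</concentration>
          <centerX>0</centerX>
          <centerY>0</centerY>
          <innerRadius>20</innerRadius>
          <outerRadius>25</outerRadius>
        </osmoticRingConf>
      </chemotaxis>
    </experimentWideConf>
    <interactionAtSpecificTime>
      <eventTime>5000</eventTime>
      <mechanotaxis>
        <directTouchConf>
          <bodyPosition>0.3</bodyPosition>
          <circumferentialAngle>0</circumferentialAngle>
          <force>1.5</force>
          <contactDuration>200</contactDuration>
        </directTouchConf>
      </mechanotaxis>
    </interactionAtSpecificTime>
    <interactionAtSpecificTime>
      <eventTime>15000</eventTime>
      <mechanotaxis>
        <plateTapConf>
          <intensity>2</intensity>
        </plateTapConf>
      </mechanotaxis>
    </interactionAtSpecificTime>
    <interactionFromt0tot1>
      <eventStartTime>20000</eventStartTime>
      <eventStopTime>30000</eventStopTime>
      <galvanotaxis>
        <electricShockConf>
          <amplitude>5</amplitude>
          <duration>500</duration>
          <frequency>10</frequency>
        </electricShockConf>
      </galvanotaxis>
    </interactionFromt0tot1>
    <interactionFromt0tot1>
      <eventStartTime>35000</eventStartTime>
      <eventStopTime>50000</eventStopTime>
      <thermotaxis>
        <temperatureChangeConf>
          <startTemp>17</startTemp>
          <endTemp>23</endTemp>
          <profile>linear</profile>
        </temperatureChangeConf>
      </thermotaxis>
    </interactionFromt0tot1>
  </experimentDefinition>
  <environmentDefinition>
    <wormStatus>
      <wormData>
        <mutationId>N2</mutationId>
        <age>1</age>
        <sex>hermaphrodite</sex>
        <stage>L1</stage>
        <hoursWithoutFood>1</hoursWithoutFood>
        <bodyLength>1</bodyLength>
        <bodyDiameter>80</bodyDiameter>
      </wormData>
      <wormLocation>
        <x>10</x>
        <y>5</y>
        <orientation>45</orientation>
      </wormLocation>
    </wormStatus>
    <plateConf>
      <shape>cylindrical</shape>
      <borderHeight>15</borderHeight>
      <radius>50</radius>
      <substrate>A</substrate>
      <dryness>1</dryness>
      <lid>false</lid>
    </plateConf>
    <obstaclesConf>
      <obstacle>
        <shape>cylinder</shape>
        <height>5</height>
        <radius>5</radius>
        <stiffness>43.2</stiffness>
        <distanceX>10</distanceX>
        <distanceY>-15</distanceY>
        <angle>30</angle>
      </obstacle>
    </obstaclesConf>
    <crowdingConf>
      <wormCount>1</wormCount>
      <distributionIndex>0</distributionIndex>
    </crowdingConf>
  </environmentDefinition>
</behavioralExperiment>
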